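#' Ungapped end-to-end alignment of short reads
#'
#' Places each full read at every possible offset of every reference (forward
#' strand; optionally also the reverse complement) and reports, per read, all
#' placements achieving the minimal mismatch count when that minimum is at
#' most `max_mismatches`. Reads with no qualifying placement yield no rows.
#' Candidate placements are generated with `max_mismatches + 1` disjoint
#' exact seeds (pigeonhole), which is equivalent to the exhaustive scan.
#'
#' @param reads character vector of read sequences, named by read id (or a
#'   data.frame with `read_id` and `seq`).
#' @param refs named character vector or [Biostrings::DNAStringSet] of
#'   reference sequences.
#' @param max_mismatches maximum mismatch count; default 2.
#' @param both_strands also search the reverse complement of each read (used
#'   for the genome pass); default FALSE.
#' @return data.frame with columns `read_id`, `ref_id`, `ref_start`,
#'   `ref_end` (0-based, half-open, BED-style), `strand` and `mismatches`.
#' @export
alignReads <- function(reads, refs, max_mismatches = 2L, both_strands = FALSE) {
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$read_id)
  if (length(refs) == 0) stop("references must be non-empty")
  refIds <- names(refs)
  refSeq <- as.character(refs)
  if (is.null(refIds)) refIds <- names(refSeq)
  if (is.null(refIds)) refIds <- as.character(seq_along(refSeq))
  ids <- names(reads)
  if (is.null(ids)) ids <- as.character(seq_along(reads))
  hits <- align_reads_cpp(unname(reads), unname(refSeq),
                          as.integer(max_mismatches), isTRUE(both_strands))
  data.frame(read_id = ids[hits$read],
             ref_id = refIds[hits$ref],
             ref_start = hits$ref_start,
             ref_end = hits$ref_end,
             strand = ifelse(hits$strand > 0, "+", "-"),
             mismatches = hits$mismatches,
             stringsAsFactors = FALSE)
}

# one row per read: fewest mismatches, ties by lexicographically smallest
# ref_id, then leftmost placement (fully deterministic)
.bestHits <- function(aln) {
  if (!nrow(aln)) return(aln)
  o <- order(aln$read_id, aln$mismatches, aln$ref_id, aln$ref_start)
  aln <- aln[o, , drop = FALSE]
  aln[!duplicated(aln$read_id), , drop = FALSE]
}

#' Quantify mature miRNAs from precursor alignments
#'
#' Two quantification rules are merged into a single mature count vector:
#' for precursors with annotated arms (knowledge-based), a read increments
#' the mature arm (`<id>-5p` / `<id>-3p`) whose interval overlaps the read
#' placement by the most nucleotides (ties go to the 5p arm); for precursors
#' without arm annotations (position-based), a read whose placement midpoint
#' lies in the 5' half of the hairpin increments `<id>_5p-Novel`, otherwise
#' `<id>_3p-Novel`. Each read counts exactly once: among its minimal-mismatch
#' placements the lexicographically smallest mature feature wins. Features
#' with zero counts are retained.
#'
#' @param aln alignment data.frame from [alignReads()] against the precursor
#'   set (rows referencing other references are ignored).
#' @param bundle a [ReferenceBundle-class] providing arms and hairpin lengths.
#' @param sample sample name for the single count column.
#' @return [SummarizedExperiment::SummarizedExperiment] with a `counts` assay
#'   (mature features x 1 sample).
#' @export
quantifyMirna <- function(aln, bundle, sample = "sample") {
  arms <- bundle@arms
  plen <- setNames(Biostrings::width(bundle@precursors),
                   names(bundle@precursors))
  features <- mirnaFeatureNames(bundle)
  aln <- aln[aln$ref_id %in% arms$precursor_id, , drop = FALSE]
  if (nrow(aln) && !all(aln$ref_id %in% names(plen)))
    stop("alignment references unknown precursor_id")

  counts <- setNames(integer(length(features)), features)
  if (nrow(aln)) {
    rowArm <- match(aln$ref_id, arms$precursor_id)
    a5s <- arms$arm5_start[rowArm]; a5e <- arms$arm5_end[rowArm]
    a3s <- arms$arm3_start[rowArm]; a3e <- arms$arm3_end[rowArm]
    annotated <- !is.na(a5s)
    feat <- character(nrow(aln))

    # knowledge-based: majority overlap in nucleotides, ties to arm5
    ov5 <- pmax(0, pmin(aln$ref_end, a5e) - pmax(aln$ref_start, a5s))
    ov3 <- pmax(0, pmin(aln$ref_end, a3e) - pmax(aln$ref_start, a3s))
    feat[annotated] <- paste0(aln$ref_id[annotated],
                              ifelse(ov5[annotated] >= ov3[annotated],
                                     "-5p", "-3p"))
    # position-based: placement midpoint vs hairpin midpoint
    mid <- (aln$ref_start + aln$ref_end) / 2
    half <- plen[aln$ref_id] / 2
    feat[!annotated] <- paste0(aln$ref_id[!annotated],
                               ifelse(mid[!annotated] < half[!annotated],
                                      "_5p-Novel", "_3p-Novel"))

    pick <- data.frame(read_id = aln$read_id, mismatches = aln$mismatches,
                       feature = feat, stringsAsFactors = FALSE)
    o <- order(pick$read_id, pick$mismatches, pick$feature)
    pick <- pick[o, , drop = FALSE]
    pick <- pick[!duplicated(pick$read_id), , drop = FALSE]
    tab <- table(pick$feature)
    counts[names(tab)] <- as.integer(tab)
  }
  m <- matrix(counts, ncol = 1, dimnames = list(features, sample))
  .countSE(m)
}

#' Count reads per annotation feature
#'
#' Each aligned read contributes exactly one count, assigned to its best hit
#' (fewest mismatches, ties broken by lexicographically smallest feature id).
#' Zero-count features are retained, so column sums equal the number of reads
#' with at least one qualifying alignment.
#'
#' @param aln alignment data.frame from [alignReads()].
#' @param features character vector of all feature ids in the set (defines
#'   the row universe).
#' @param sample sample name for the single count column.
#' @param rowData optional data.frame of per-feature metadata (e.g. biotype),
#'   with rownames matching `features`.
#' @return [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay.
#' @export
quantifyAnnotationCounts <- function(aln, features, sample = "sample",
                                     rowData = NULL) {
  counts <- setNames(integer(length(features)), features)
  if (nrow(aln)) {
    best <- .bestHits(aln)
    tab <- table(best$ref_id)
    counts[names(tab)] <- as.integer(tab)
  }
  m <- matrix(counts, ncol = 1, dimnames = list(features, sample))
  .countSE(m, rowData)
}

#' Hierarchical triage of preprocessed reads
#'
#' Sequential alignment passes in the pipeline's order: (1) human small RNA
#' annotations (miRNA precursors plus sncRNAs, annotation strand only),
#' (2) the host genome (both strands), (3) diet miRNAs; reads left unmapped
#' become the candidate-microbial pool. Each read is classified at the first
#' stage it maps to, so classes are mutually exclusive and exhaustive.
#'
#' @param reads data.frame with `read_id`, `seq` (preprocessed reads) or a
#'   named character vector.
#' @param bundle a [ReferenceBundle-class].
#' @param max_mismatches per-stage mismatch cap; default 2.
#' @param sample sample name.
#' @return A [TriageResult-class]; stage-1 and stage-3 alignments are kept so
#'   quantification does not need to re-align.
#' @export
triageReads <- function(reads, bundle, max_mismatches = 2L, sample = "sample") {
  if (is.data.frame(reads)) reads <- setNames(reads$seq, reads$read_id)
  ids <- names(reads)
  cls <- setNames(rep("candidate_microbial", length(reads)), ids)

  stage1refs <- c(as.character(bundle@precursors), as.character(bundle@sncrnas))
  aln1 <- alignReads(reads, stage1refs, max_mismatches, both_strands = FALSE)
  cls[unique(aln1$read_id)] <- "hsa_srna"

  pool <- reads[cls == "candidate_microbial"]
  if (length(pool)) {
    aln2 <- alignReads(pool, setNames(as.character(bundle@hostGenome), "host"),
                       max_mismatches, both_strands = TRUE)
    cls[unique(aln2$read_id)] <- "hsa_genome"
  }

  pool <- reads[cls == "candidate_microbial"]
  aln3 <- if (length(pool) && length(bundle@dietMirnas)) {
    a <- alignReads(pool, as.character(bundle@dietMirnas),
                    max_mismatches, both_strands = FALSE)
    cls[unique(a$read_id)] <- "diet"
    a
  } else {
    data.frame(read_id = character(), ref_id = character(),
               ref_start = integer(), ref_end = integer(),
               strand = character(), mismatches = integer(),
               stringsAsFactors = FALSE)
  }

  counts <- setNames(integer(length(.CLASSES)), .CLASSES)
  tab <- table(cls)
  counts[names(tab)] <- as.integer(tab)
  fr <- if (sum(counts)) counts / sum(counts) else counts * 0

  methods::new("TriageResult",
    sample = sample,
    assignments = data.frame(read_id = ids, class = unname(cls),
                             stringsAsFactors = FALSE),
    counts = counts,
    fractions = as.numeric(fr) |> setNames(names(fr)),
    srnaAlignments = aln1,
    dietAlignments = aln3)
}
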