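#' Collapse bacterial sRNA annotations into a nonredundant set
#'
#' Annotations whose species falls at or below the mean-DNA-abundance
#' threshold are removed, sequences of length >= `max_length` are removed
#' (strictly shorter sequences are kept), and the identical survivors are
#' merged into single entries with full member bookkeeping. Entry ids are
#' FNV-1a hashes of the sequence, so the result is independent of input
#' order.
#'
#' @param annotations data.frame with `annotation_id`, `species_id`,
#'   `sequence` (see [bsrnaAnnotations()]).
#' @param dnaAbundance species-by-sample matrix of DNA-derived percent
#'   abundances; rownames are species ids (or names matching `species_id`).
#' @param min_species_abundance keep species whose unweighted mean abundance
#'   across samples is strictly greater than this (percent); default 0.01.
#' @param max_length sequences of this length or longer are excluded
#'   (strict `<`); default 80.
#' @return A [NonredundantSRNASet-class].
#' @export
collapseAnnotations <- function(annotations, dnaAbundance,
                                min_species_abundance = 0.01,
                                max_length = 80L) {
  meanAb <- rowMeans(dnaAbundance)
  keepSpecies <- names(meanAb)[meanAb > min_species_abundance]
  ann <- annotations[annotations$species_id %in% keepSpecies &
                       nchar(annotations$sequence) < max_length, , drop = FALSE]
  if (!nrow(ann)) {
    return(methods::new("NonredundantSRNASet",
      entries = data.frame(entry_id = character(), sequence = character(),
                           n_members = integer(), stringsAsFactors = FALSE),
      members = data.frame(entry_id = character(), annotation_id = character(),
                           species_id = character(), stringsAsFactors = FALSE)))
  }
  seqs <- sort(unique(ann$sequence))
  ids <- paste0("nr_", fnvHash(seqs))
  lookup <- setNames(ids, seqs)
  members <- data.frame(entry_id = unname(lookup[ann$sequence]),
                        annotation_id = ann$annotation_id,
                        species_id = ann$species_id,
                        stringsAsFactors = FALSE)
  members <- members[order(members$entry_id, members$annotation_id), , drop = FALSE]
  rownames(members) <- NULL
  entries <- data.frame(entry_id = ids, sequence = seqs,
                        n_members = as.integer(table(members$entry_id)[ids]),
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$entry_id), , drop = FALSE]
  rownames(entries) <- NULL
  methods::new("NonredundantSRNASet", entries = entries, members = members)
}

#' Quantify bacterial sRNA expression
#'
#' Aligns candidate-microbial reads against the nonredundant entry sequences
#' and counts with the same contract as [quantifyAnnotationCounts()]: each
#' read contributes at most one count, to its best-hit entry.
#'
#' @param reads candidate-microbial pool: named character vector of read
#'   sequences or data.frame with `read_id`, `seq`.
#' @param nrset a [NonredundantSRNASet-class].
#' @param max_mismatches mismatch cap for the alignment; default 2.
#' @param sample sample name.
#' @return [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay (entries x 1 sample).
#' @export
quantifyBsrna <- function(reads, nrset, max_mismatches = 2L, sample = "sample") {
  entries <- nrset@entries
  if (!nrow(entries) || !length(reads)) {
    m <- matrix(integer(nrow(entries)), ncol = 1,
                dimnames = list(entries$entry_id, sample))
    return(.countSE(m))
  }
  aln <- alignReads(reads, setNames(entries$sequence, entries$entry_id),
                    max_mismatches, both_strands = FALSE)
  quantifyAnnotationCounts(aln, entries$entry_id, sample)
}

#' Transcription-rate ratios between RNA- and DNA-derived abundances
#'
#' Per species and sample, the ratio of the sRNA-derived relative abundance
#' to the DNA-derived relative abundance (and its log2). Species with zero
#' or missing DNA abundance in a sample are flagged undefined and excluded
#' from medians.
#'
#' @param rnaAbundance,dnaAbundance species-by-sample matrices of percent
#'   abundances at species rank (see [abundanceMatrix()]); rows are matched
#'   by name, columns by sample.
#' @return data.frame with `species`, `sample`, `rna_abundance`,
#'   `dna_abundance`, `ratio`, `log2_ratio`, `defined`.
#' @export
transcriptionRate <- function(rnaAbundance, dnaAbundance) {
  samples <- intersect(colnames(rnaAbundance), colnames(dnaAbundance))
  if (!length(samples)) stop("no shared samples between RNA and DNA profiles")
  species <- union(rownames(rnaAbundance), rownames(dnaAbundance))
  get <- function(m, sp, s) if (sp %in% rownames(m)) m[sp, s] else 0
  out <- do.call(rbind, lapply(samples, function(s) {
    rna <- vapply(species, get, numeric(1), m = rnaAbundance, s = s)
    dna <- vapply(species, get, numeric(1), m = dnaAbundance, s = s)
    defined <- dna > 0
    ratio <- ifelse(defined, rna / dna, NA_real_)
    data.frame(species = species, sample = s, rna_abundance = rna,
               dna_abundance = dna, ratio = ratio,
               log2_ratio = log2(ratio), defined = defined,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cohort summary of transcription rates
#'
#' Retains species whose median per-sample ratio (undefined values dropped)
#' is strictly greater than `min_median` (set `direction = "<"` to select
#' low-transcription species instead).
#'
#' @param rates data.frame from [transcriptionRate()].
#' @param min_median threshold on the median ratio; default 1.
#' @param direction ">" (default) or "<".
#' @return data.frame with `species`, `median_ratio`, `n_defined`, filtered
#'   and sorted by median ratio.
#' @export
summarizeTranscriptionRates <- function(rates, min_median = 1, direction = ">") {
  direction <- match.arg(direction, c(">", "<"))
  sp <- split(rates$ratio[rates$defined], rates$species[rates$defined])
  med <- vapply(sp, median, numeric(1))
  out <- data.frame(species = names(med), median_ratio = unname(med),
                    n_defined = unname(lengths(sp)), stringsAsFactors = FALSE)
  keep <- if (direction == ">") out$median_ratio > min_median
          else out$median_ratio < min_median
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$median_ratio), , drop = FALSE]
  rownames(out) <- NULL
  out
}
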