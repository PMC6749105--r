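#' @importClassesFrom Biostrings DNAStringSet DNAString
NULL

.checkDna <- function(x, what) {
  bad <- grepl("[^ACGT]", as.character(x))
  if (any(bad))
    return(sprintf("%s: %d sequence(s) contain characters outside {A,C,G,T}",
                   what, sum(bad)))
  NULL
}

#' Reference bundle for the triage pipeline
#'
#' Holds every reference set the hierarchical read triage consumes: miRNA
#' precursor hairpins (with optional 5p/3p arm intervals), human small
#' noncoding RNAs with biotypes, a single-contig host genome decoy with the
#' coordinates of the small RNA loci embedded in it, dietary miRNAs, microbial
#' species genomes, a rooted taxonomy, and bacterial sRNA annotations whose
#' sequences are substrings of their species' genome.
#'
#' Arm intervals and host feature loci are 0-based half-open, matching the
#' coordinate convention of [alignReads()].
#'
#' @slot precursors [Biostrings::DNAStringSet] of precursor hairpins, named by
#'   precursor id.
#' @slot arms data.frame with columns `precursor_id`, `arm5_start`, `arm5_end`,
#'   `arm3_start`, `arm3_end` (NA for precursors without arm annotations).
#' @slot sncrnas [Biostrings::DNAStringSet] of sncRNA sequences, named by id.
#' @slot sncrnaBiotype named character vector of biotypes (tRNA, piRNA, ...).
#' @slot hostGenome [Biostrings::DNAString], single-contig host decoy.
#' @slot hostFeatureLoci data.frame (`id`, `type`, `start`, `end`) of small RNA
#'   loci embedded in the host genome.
#' @slot dietMirnas [Biostrings::DNAStringSet] of diet-derived miRNAs.
#' @slot genomes [Biostrings::DNAStringSet] of species genomes, named by the
#'   species taxon id.
#' @slot taxonomy data.frame (`taxon_id`, `name`, `rank`, `parent_id`); the
#'   root is its own parent.
#' @slot bsrnaAnnotations data.frame (`annotation_id`, `species_id`,
#'   `sequence`).
#' @seealso [generateReferenceBundle()], [triageReads()]
#' @export
setClass("ReferenceBundle",
  representation(
    precursors = "DNAStringSet",
    arms = "data.frame",
    sncrnas = "DNAStringSet",
    sncrnaBiotype = "character",
    hostGenome = "DNAString",
    hostFeatureLoci = "data.frame",
    dietMirnas = "DNAStringSet",
    genomes = "DNAStringSet",
    taxonomy = "data.frame",
    bsrnaAnnotations = "data.frame"
  )
)

setValidity("ReferenceBundle", function(object) {
  msgs <- character()
  for (nm in c("precursors", "sncrnas", "dietMirnas", "genomes")) {
    m <- .checkDna(slot(object, nm), nm)
    if (!is.null(m)) msgs <- c(msgs, m)
  }
  m <- .checkDna(object@hostGenome, "hostGenome")
  if (!is.null(m)) msgs <- c(msgs, m)

  tax <- object@taxonomy
  tv <- tryCatch({ validateTaxonomy(tax); NULL }, error = function(e) conditionMessage(e))
  if (!is.null(tv)) msgs <- c(msgs, tv)

  sp <- tax$taxon_id[tax$rank == "species"]
  if (!all(names(object@genomes) %in% sp))
    msgs <- c(msgs, "every genome must be named by a rank=\"species\" taxon_id")

  ann <- object@bsrnaAnnotations
  if (nrow(ann)) {
    if (!all(ann$species_id %in% names(object@genomes)))
      msgs <- c(msgs, "bsRNA annotations reference unknown species")
    gen <- as.character(object@genomes)
    ok <- vapply(seq_len(nrow(ann)), function(i)
      grepl(ann$sequence[i], gen[[ann$species_id[i]]], fixed = TRUE), logical(1))
    if (!all(ok))
      msgs <- c(msgs, "bsRNA sequences must be substrings of their species' genome")
  }
  if (length(msgs)) msgs else TRUE
})

#' k-mer to lowest-common-ancestor database
#'
#' The state of the taxonomic classification engine: a rooted taxonomy and a
#' map from canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement) to the lowest common ancestor of all species whose genomes
#' contain them.
#'
#' @slot k k-mer size in nucleotides (default 31 in [buildKmerLcaDb()]).
#' @slot kmer character vector of canonical k-mers (sorted, deterministic).
#' @slot taxon character vector of taxon ids parallel to `kmer`.
#' @slot taxonomy the taxonomy data.frame the database was built against.
#' @seealso [buildKmerLcaDb()], [classifyReads()]
#' @export
setClass("KmerLCADB",
  representation(k = "integer", kmer = "character", taxon = "character",
                 taxonomy = "data.frame"))

setValidity("KmerLCADB", function(object) {
  msgs <- character()
  if (length(object@kmer) != length(object@taxon))
    msgs <- c(msgs, "kmer and taxon must have equal length")
  if (!all(object@taxon %in% object@taxonomy$taxon_id))
    msgs <- c(msgs, "every stored taxon_id must exist in the taxonomy")
  if (length(object@kmer) && !all(nchar(object@kmer) == object@k))
    msgs <- c(msgs, "all k-mers must have length k")
  if (length(msgs)) msgs else TRUE
})

#' Per-sample taxonomic profile
#'
#' Clade read counts and per-rank relative abundances (percent) for one
#' sample. The clade count of a taxon is the number of reads assigned to the
#' taxon or any of its descendants; within each rank, abundances of taxa with
#' nonzero counts sum to 100. Serializes to MetaPhlAn (mpa) text format via
#' [writeMpa()].
#'
#' @slot sample sample identifier.
#' @slot clades data.frame (`taxon_id`, `name`, `rank`, `clade_count`,
#'   `abundance`), one row per taxon with a nonzero clade count.
#' @slot totalClassified total number of classified reads (the relative
#'   abundance denominator).
#' @seealso [taxProfile()], [writeMpa()]
#' @export
setClass("TaxProfile",
  representation(sample = "character", clades = "data.frame",
                 totalClassified = "integer"))

setValidity("TaxProfile", function(object) {
  msgs <- character()
  cl <- object@clades
  if (nrow(cl) && object@totalClassified > 0L) {
    # per-rank sums cannot exceed 100 and equal 100 exactly at ranks at or
    # above every assignment (reads assigned above a rank drop out of it)
    for (r in unique(cl$rank)) {
      s <- sum(cl$abundance[cl$rank == r])
      if (s > 100 + 1e-6)
        msgs <- c(msgs, sprintf("abundances at rank %s sum to %.8f > 100", r, s))
    }
    top <- sum(cl$abundance[cl$rank == cl$rank[which.min(match(cl$rank, .RANKS))]])
    if (abs(top - 100) > 1e-6)
      msgs <- c(msgs, "top-rank abundances must sum to 100")
    if (any(cl$clade_count <= 0))
      msgs <- c(msgs, "clade counts must be positive for reported clades")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of hierarchical read triage
#'
#' Each preprocessed read is assigned to the first reference class it maps to:
#' human small RNA annotations (`hsa_srna`), human genome (`hsa_genome`),
#' dietary miRNAs (`diet`), or the remaining candidate-microbial pool
#' (`candidate_microbial`). Classes are mutually exclusive and exhaustive.
#'
#' @slot sample sample identifier.
#' @slot assignments data.frame (`read_id`, `class`).
#' @slot counts named integer vector of per-class read counts.
#' @slot fractions named numeric vector, `counts / sum(counts)`.
#' @slot srnaAlignments alignments of `hsa_srna` reads against the combined
#'   precursor + sncRNA reference (input to [quantifyMirna()] and
#'   [quantifyAnnotationCounts()]).
#' @slot dietAlignments alignments of `diet` reads against diet miRNAs.
#' @seealso [triageReads()]
#' @export
setClass("TriageResult",
  representation(sample = "character", assignments = "data.frame",
                 counts = "integer", fractions = "numeric",
                 srnaAlignments = "data.frame", dietAlignments = "data.frame"))

setValidity("TriageResult", function(object) {
  msgs <- character()
  if (!identical(sort(names(object@counts)), sort(.CLASSES)))
    msgs <- c(msgs, "counts must cover exactly the four triage classes")
  if (sum(object@counts) != nrow(object@assignments))
    msgs <- c(msgs, "class counts must sum to the number of assigned reads")
  if (sum(object@counts) > 0 && abs(sum(object@fractions) - 1) > 1e-9)
    msgs <- c(msgs, "fractions must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' Nonredundant bacterial sRNA annotation set
#'
#' Identical annotation sequences (which occur because the same sRNA is
#' annotated to different species or strains) are merged into single entries
#' with full member bookkeeping. Entry identifiers are FNV-1a 64-bit hashes of
#' the sequence.
#'
#' @slot entries data.frame (`entry_id`, `sequence`, `n_members`).
#' @slot members data.frame (`entry_id`, `annotation_id`, `species_id`).
#' @seealso [collapseAnnotations()], [quantifyBsrna()]
#' @export
setClass("NonredundantSRNASet",
  representation(entries = "data.frame", members = "data.frame"))

setValidity("NonredundantSRNASet", function(object) {
  msgs <- character()
  if (anyDuplicated(object@entries$sequence))
    msgs <- c(msgs, "entry sequences must be unique")
  if (!all(object@members$entry_id %in% object@entries$entry_id))
    msgs <- c(msgs, "members reference unknown entries")
  if (length(msgs)) msgs else TRUE
})
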