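#' Trim the 3' adapter from reads
#'
#' Finds the best semi-global alignment of the adapter (or of an adapter
#' prefix at the read's 3' end) under an edit-distance model (mismatches,
#' insertions and deletions all count) and removes everything from the
#' alignment start to the read end. An occurrence qualifies when its edit
#' distance is at most `floor(max_error_rate * aligned_adapter_length)` and
#' the aligned adapter length is at least `min_overlap`. Among qualifying
#' occurrences the one with the lowest error rate is chosen, ties going to
#' the leftmost start (the longer trim). Reads without a qualifying
#' occurrence (including empty reads) are returned unchanged.
#'
#' @param reads data.frame with columns `read_id`, `seq`, `qual` (see
#'   [readFastq()]), or a character vector of sequences.
#' @param adapter adapter sequence (non-empty DNA string).
#' @param max_error_rate maximum error rate relative to the aligned adapter
#'   length; default 0.15.
#' @param min_overlap minimum aligned adapter length in nt; default 3.
#' @return Object of the same shape as `reads` with trimmed `seq` (and `qual`
#'   truncated in step).
#' @examples
#' trimAdapter(c("ACGTACGTACGTACGTACGTAGATCGGAAGAGCACACGTCT"),
#'             adapter = "AGATCGGAAGAGCACACGTCT")
#' @export
trimAdapter <- function(reads, adapter, max_error_rate = 0.15, min_overlap = 3L) {
  vec <- is.character(reads)
  seqs <- if (vec) reads else reads$seq
  keep <- trim_adapter_cpp(seqs, adapter, max_error_rate, as.integer(min_overlap))
  trimmed <- substr(seqs, 1L, keep)
  if (vec) return(trimmed)
  reads$seq <- trimmed
  reads$qual <- substr(reads$qual, 1L, keep)
  reads
}

#' Discard reads shorter than a minimum length
#'
#' @param reads data.frame with `read_id`, `seq`, `qual` columns (or a
#'   character vector).
#' @param min_length minimum kept read length in nt; default 14. Reads
#'   strictly shorter are discarded.
#' @return List with elements `reads` (the kept reads, same shape as input)
#'   and `report`, a one-row data.frame with `n_input`, `n_kept`,
#'   `n_discarded_short` and `mean_length_after`.
#' @export
filterReads <- function(reads, min_length = 14L) {
  seqs <- if (is.character(reads)) reads else reads$seq
  keep <- nchar(seqs) >= min_length
  kept <- if (is.character(reads)) reads[keep] else reads[keep, , drop = FALSE]
  if (!is.character(kept)) rownames(kept) <- NULL
  report <- data.frame(
    n_input = length(seqs),
    n_kept = sum(keep),
    n_discarded_short = sum(!keep),
    mean_length_after = if (any(keep)) mean(nchar(seqs[keep])) else NA_real_)
  list(reads = kept, report = report)
}

#' Preprocess a read set: adapter trimming and length filtering
#'
#' By default reads are trimmed first and length-filtered afterwards (trimming
#' shortens reads, so filtering post-trim is the conservative superset); set
#' `trim_first = FALSE` to filter on raw lengths before trimming.
#'
#' @inheritParams trimAdapter
#' @inheritParams filterReads
#' @param trim_first logical; order of the two steps.
#' @return List with `reads` and `report` (as [filterReads()], plus
#'   `n_trimmed`, the number of reads shortened by adapter removal).
#' @export
preprocessReads <- function(reads, adapter, max_error_rate = 0.15,
                            min_overlap = 3L, min_length = 14L,
                            trim_first = TRUE) {
  lenBefore <- nchar(if (is.character(reads)) reads else reads$seq)
  if (trim_first) {
    trimmed <- trimAdapter(reads, adapter, max_error_rate, min_overlap)
    n_trimmed <- sum(nchar(if (is.character(trimmed)) trimmed else trimmed$seq)
                     < lenBefore)
    out <- filterReads(trimmed, min_length)
  } else {
    flt <- filterReads(reads, min_length)
    lenBefore <- nchar(if (is.character(flt$reads)) flt$reads else flt$reads$seq)
    trimmed <- trimAdapter(flt$reads, adapter, max_error_rate, min_overlap)
    n_trimmed <- sum(nchar(if (is.character(trimmed)) trimmed else trimmed$seq)
                     < lenBefore)
    out <- list(reads = trimmed, report = flt$report)
    out$report$mean_length_after <-
      mean(nchar(if (is.character(trimmed)) trimmed else trimmed$seq))
  }
  out$report$n_trimmed <- n_trimmed
  out
}
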