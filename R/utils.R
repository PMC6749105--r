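# Shared low-level helpers: random sequence generation, reverse complement,
# FASTQ/FASTA IO (through Biostrings).

# one random DNA string
.randSeq <- function(len) {
  paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

# many random DNA strings of the given lengths, drawn in one block
.randSeqs <- function(lens) {
  if (!length(lens)) return(character())
  total <- sum(lens)
  if (total == 0) return(rep("", length(lens)))
  big <- paste(sample(.BASES, total, replace = TRUE), collapse = "")
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  out <- substring(big, starts, ends)
  out[lens == 0] <- ""
  out
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a FASTQ file into a read table
#'
#' @param path path to an (uncompressed or gzipped) FASTQ file.
#' @return data.frame with columns `read_id`, `seq`, `qual`.
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read table to FASTQ
#'
#' @param reads data.frame with columns `read_id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

.writeFasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(as.character(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # keep only the first token of the header as the id
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

# named-vector -> single-column count assembly
.bindCounts <- function(vecs, features, samples) {
  m <- matrix(0L, nrow = length(features), ncol = length(vecs),
              dimnames = list(features, samples))
  for (j in seq_along(vecs)) {
    v <- vecs[[j]]
    if (length(v)) m[names(v), j] <- as.integer(v)
  }
  m
}

.countSE <- function(counts, rowData = NULL) {
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(counts = counts))
  if (!is.null(rowData))
    SummarizedExperiment::rowData(se) <- rowData[rownames(counts), , drop = FALSE]
  se
}

#' Extract the counts assay from a SummarizedExperiment or pass a matrix through
#'
#' @param x matrix or SummarizedExperiment with a `counts` assay.
#' @return Integer/numeric matrix.
#' @export
countsOf <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    return(SummarizedExperiment::assay(x, "counts"))
  as.matrix(x)
}

#' FNV-1a 64-bit sequence hash
#'
#' Hex-encoded 64-bit FNV-1a hash, used for nonredundant-entry identifiers and
#' run-configuration fingerprints.
#'
#' @param x character vector.
#' @return Character vector of 16-hex-digit hashes.
#' @export
fnvHash <- function(x) fnv1a64_cpp(as.character(x))
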