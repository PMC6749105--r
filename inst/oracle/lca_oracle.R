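# Brute-force reference implementation of the k-mer LCA classifier:
# direct substring k-mer lookup per genome plus exhaustive root-to-leaf path
# scoring. Deliberately independent of the package's C++ engine; used as the
# oracle in the acceptance script.

lcaOracleRevComp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

lcaOracleLca <- function(tax, ids) {
  parent <- setNames(tax$parent_id, tax$taxon_id)
  path <- function(id) {
    p <- id
    while (parent[[id]] != id) { id <- parent[[id]]; p <- c(p, id) }
    rev(p)
  }
  paths <- lapply(unique(ids), path)
  lca <- NULL
  for (i in seq_len(min(lengths(paths)))) {
    lev <- vapply(paths, `[[`, character(1), i)
    if (all(lev == lev[1])) lca <- lev[1] else break
  }
  lca
}

lcaOracleClassifier <- function(genomes, tax, k = 31L, min_len = 31L) {
  gplus <- paste(genomes, vapply(genomes, lcaOracleRevComp, character(1)),
                 sep = "NN")
  parent <- setNames(tax$parent_id, tax$taxon_id)
  ancestors <- function(id) {
    p <- id
    while (parent[[id]] != id) { id <- parent[[id]]; p <- c(p, id) }
    p
  }
  leaves <- setdiff(tax$taxon_id,
                    tax$parent_id[tax$parent_id != tax$taxon_id])
  function(read) {
    if (nchar(read) < min_len)
      return(list(taxon = NA_character_, unique = TRUE))
    n <- nchar(read)
    kmers <- substring(read, 1:(n - k + 1), k:n)
    rc <- vapply(kmers, lcaOracleRevComp, character(1))
    kmers <- pmin(kmers, rc)
    votes <- setNames(numeric(nrow(tax)), tax$taxon_id)
    for (x in kmers) {
      insp <- names(genomes)[grepl(x, gplus, fixed = TRUE) |
                               grepl(lcaOracleRevComp(x), gplus, fixed = TRUE)]
      if (!length(insp)) next
      t <- lcaOracleLca(tax, insp)
      votes[t] <- votes[t] + 1
    }
    if (sum(votes) == 0) return(list(taxon = NA_character_, unique = TRUE))
    w <- vapply(leaves, function(l) sum(votes[ancestors(l)]), numeric(1))
    best <- leaves[w == max(w) & w > 0]
    list(taxon = if (length(best) == 1) best else lcaOracleLca(tax, best),
         unique = length(best) == 1)
  }
}
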