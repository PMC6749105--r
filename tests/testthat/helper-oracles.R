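# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# --- adapter trimming: per-start semi-global DP ----------------------------
# returns the number of bases kept (== read length when nothing qualifies)
oracleTrim <- function(read, adapter, rate = 0.15, min_overlap = 3L) {
  n <- nchar(read); m <- nchar(adapter)
  if (n == 0) return(0L)
  A <- strsplit(adapter, "")[[1]]
  R <- strsplit(read, "")[[1]]
  best_rate <- Inf; best_start <- n
  for (s in 0:(n - 1)) {
    sub <- R[(s + 1):n]
    L <- length(sub)
    D <- matrix(Inf, m + 1, L + 1)
    D[, 1] <- 0:m        # adapter deletions at the alignment start
    D[1, 1] <- 0
    # leading read insertions are a later start, not part of this alignment
    for (j in 1:m) for (i in 1:L) {
      D[j + 1, i + 1] <- min(D[j, i] + (A[j] != sub[i]),
                             D[j, i + 1] + 1,
                             D[j + 1, i] + 1)
    }
    cand <- rbind(
      data.frame(l = m, c = suppressWarnings(min(D[m + 1, ]))),   # full adapter, any end
      if (m > 1) data.frame(l = 1:(m - 1), c = D[2:m, L + 1]) else NULL) # prefix at read end
    cand <- cand[is.finite(cand$c) & cand$l >= min_overlap &
                   cand$c <= floor(rate * cand$l + 1e-9), , drop = FALSE]
    if (nrow(cand)) {
      r <- min(cand$c / cand$l)
      if (r < best_rate - 1e-12) { best_rate <- r; best_start <- s }
    }
  }
  if (is.finite(best_rate)) best_start else n
}

# --- ungapped alignment: exhaustive scan -----------------------------------
oracleRevComp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

oracleAlign <- function(read, refs, max_mm = 2L, both_strands = FALSE) {
  hits <- list()
  scan <- function(seq, strand) {
    rl <- nchar(seq)
    rv <- strsplit(seq, "")[[1]]
    for (ri in seq_along(refs)) {
      ref <- strsplit(refs[[ri]], "")[[1]]
      if (length(ref) < rl) next
      for (p in 0:(length(ref) - rl)) {
        mm <- sum(rv != ref[(p + 1):(p + rl)])
        if (mm <= max_mm)
          hits[[length(hits) + 1]] <<- data.frame(
            ref_id = names(refs)[ri], ref_start = p, ref_end = p + rl,
            strand = strand, mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  scan(read, "+")
  if (both_strands) scan(oracleRevComp(read), "-")
  if (!length(hits)) return(NULL)
  out <- do.call(rbind, hits)
  out[out$mismatches == min(out$mismatches), , drop = FALSE]
}

# --- Benjamini-Hochberg step-up by definition -------------------------------
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) q[i] <- min((m / (i:m)) * sorted[i:m], 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# --- k-mer LCA classification: substring lookup + exhaustive path scoring ---
oracleKmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1), k:n)
}

oracleCanonical <- function(kmers) {
  rc <- vapply(kmers, oracleRevComp, character(1))
  pmin(kmers, rc)
}

# genomes: named character (species taxon ids); returns function(read) ->
# list(taxon, unique)
oracleClassifier <- function(genomes, tax, k = 31L, min_len = 31L) {
  gplus <- paste(genomes, vapply(genomes, oracleRevComp, character(1)),
                 sep = "NN")
  parent <- setNames(tax$parent_id, tax$taxon_id)
  ancestors <- function(id) {
    p <- id
    while (parent[[id]] != id) { id <- parent[[id]]; p <- c(p, id) }
    p
  }
  leaves <- setdiff(tax$taxon_id, tax$parent_id[tax$parent_id != tax$taxon_id])
  function(read) {
    if (nchar(read) < min_len) return(list(taxon = NA_character_, unique = TRUE))
    km <- oracleCanonical(oracleKmers(read, k))
    votes <- setNames(numeric(nrow(tax)), tax$taxon_id)
    for (x in km) {
      insp <- names(genomes)[grepl(x, gplus, fixed = TRUE) |
                               grepl(oracleRevComp(x), gplus, fixed = TRUE)]
      if (!length(insp)) next
      t <- lcaTaxon(tax, insp)
      votes[t] <- votes[t] + 1
    }
    if (sum(votes) == 0) return(list(taxon = NA_character_, unique = TRUE))
    w <- vapply(leaves, function(l) sum(votes[ancestors(l)]), numeric(1))
    best <- leaves[w == max(w) & w > 0]
    list(taxon = if (length(best) == 1) best else lcaTaxon(tax, best),
         unique = length(best) == 1)
  }
}

# --- AUC via trapezoidal ROC integration ------------------------------------
oracleAucTrapezoid <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[labels] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(scores[!labels] >= t), numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
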