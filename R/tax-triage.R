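#' Validate a taxonomy table
#'
#' Checks that the table is a rooted tree (exactly one node that is its own
#' parent), that every parent exists, that each node's rank is strictly
#' deeper than its parent's, and that species are leaves.
#'
#' @param tax data.frame with columns `taxon_id`, `name`, `rank`, `parent_id`.
#' @return `tax`, invisibly; errors with a structural message otherwise.
#' @export
validateTaxonomy <- function(tax) {
  need <- c("taxon_id", "name", "rank", "parent_id")
  if (!all(need %in% names(tax)))
    stop("taxonomy must have columns taxon_id, name, rank, parent_id")
  if (anyDuplicated(tax$taxon_id)) stop("duplicate taxon_id in taxonomy")
  if (!all(tax$rank %in% .RANKS))
    stop("taxonomy ranks must be in: ", paste(.RANKS, collapse = ", "))
  root <- tax$taxon_id == tax$parent_id
  if (sum(root) != 1) stop("taxonomy must have exactly one root (self-parent)")
  if (!all(tax$parent_id %in% tax$taxon_id))
    stop("orphan node: parent_id not present in taxonomy")
  depth <- setNames(match(tax$rank, .RANKS), tax$taxon_id)
  pd <- depth[tax$parent_id]
  if (!all(root | depth[tax$taxon_id] > pd))
    stop("each node's rank must be strictly deeper than its parent's")
  kids <- tax$parent_id[!root]
  if (any(tax$taxon_id[tax$rank == "species"] %in% kids))
    stop("species must be leaves")
  # cycle check: walking up from every node must reach the root
  parent <- setNames(tax$parent_id, tax$taxon_id)
  for (id in tax$taxon_id) {
    seen <- 0L; cur <- id
    while (parent[[cur]] != cur) {
      cur <- parent[[cur]]
      seen <- seen + 1L
      if (seen > nrow(tax)) stop("cycle detected in taxonomy")
    }
  }
  invisible(tax)
}

# integer encoding of a taxonomy for the C++ engine
.taxIndex <- function(tax) {
  idx <- seq_len(nrow(tax))
  names(idx) <- tax$taxon_id
  list(idx = idx, parent = unname(idx[tax$parent_id]))
}

#' Lowest common ancestor of taxa
#'
#' @param tax taxonomy data.frame (see [validateTaxonomy()]).
#' @param ids character vector of taxon ids.
#' @return The taxon id of the LCA.
#' @export
lcaTaxon <- function(tax, ids) {
  parent <- setNames(tax$parent_id, tax$taxon_id)
  path <- function(id) {
    p <- id
    while (parent[[id]] != id) { id <- parent[[id]]; p <- c(p, id) }
    rev(p)
  }
  paths <- lapply(unique(ids), path)
  minlen <- min(lengths(paths))
  lca <- NULL
  for (i in seq_len(minlen)) {
    lev <- vapply(paths, `[[`, character(1), i)
    if (all(lev == lev[1])) lca <- lev[1] else break
  }
  lca
}

#' Build a k-mer to LCA database from genomes
#'
#' Every canonical k-mer present in the genome of species set S maps to
#' LCA(S). Canonical form is the lexicographic minimum of the k-mer and its
#' reverse complement, so classification is strand-insensitive. Output order
#' is deterministic (sorted k-mers).
#'
#' @param genomes named character vector or [Biostrings::DNAStringSet];
#'   names are species taxon ids present in `tax`.
#' @param tax taxonomy data.frame.
#' @param k k-mer size in nt (max 31); default 31, consistent with the
#'   >= 31 nt read-length rule of [classifyReads()].
#' @return A [KmerLCADB-class].
#' @export
buildKmerLcaDb <- function(genomes, tax, k = 31L) {
  validateTaxonomy(tax)
  gnames <- names(genomes)
  genomes <- as.character(genomes)
  names(genomes) <- gnames
  if (length(genomes) && is.null(names(genomes)))
    stop("genomes must be named by species taxon id")
  sp <- tax$taxon_id[tax$rank == "species"]
  if (!all(names(genomes) %in% sp))
    stop("genome without a rank=\"species\" taxonomy node: ",
         paste(setdiff(names(genomes), sp), collapse = ", "))
  ti <- .taxIndex(tax)
  if (length(genomes)) {
    db <- build_kmer_lca_cpp(unname(genomes),
                             unname(ti$idx[names(genomes)]), ti$parent,
                             as.integer(k))
    kmer <- db$kmer
    taxon <- tax$taxon_id[db$taxon]
  } else {
    kmer <- character(0); taxon <- character(0)
  }
  methods::new("KmerLCADB", k = as.integer(k), kmer = kmer, taxon = taxon,
               taxonomy = tax)
}

#' Classify reads with the k-mer LCA engine
#'
#' Reads shorter than `min_length` are unclassified regardless of content.
#' Otherwise each canonical k-mer of the read votes for its database taxon
#' (k-mers absent from the database are ignored) and the read is assigned to
#' the leaf of the root-to-leaf path that maximizes the summed votes along
#' the path; ties are resolved conservatively to the LCA of the tied leaves.
#' Reads with zero k-mer hits are unclassified.
#'
#' @param reads character vector of read sequences (or data.frame with
#'   `seq`).
#' @param db a [KmerLCADB-class].
#' @param min_length minimum read length in nt for classification;
#'   default 31.
#' @return Character vector of taxon ids (NA for unclassified), parallel to
#'   `reads`.
#' @export
classifyReads <- function(reads, db, min_length = 31L) {
  if (is.data.frame(reads)) reads <- reads$seq
  tax <- db@taxonomy
  ti <- .taxIndex(tax)
  res <- classify_reads_cpp(unname(as.character(reads)), db@kmer,
                            unname(ti$idx[db@taxon]), ti$parent,
                            db@k, as.integer(min_length))
  out <- rep(NA_character_, length(res))
  hit <- !is.na(res)
  out[hit] <- tax$taxon_id[res[hit]]
  out
}

#' Taxonomic profile from read classifications
#'
#' The clade count of taxon t is the number of reads assigned to t or any of
#' its descendants; the rank-level relative abundance of t is
#' `100 * clade_count(t) / total classified reads` (unclassified reads are
#' excluded from the denominator).
#'
#' @param assignments character vector of taxon ids (NA = unclassified), as
#'   returned by [classifyReads()].
#' @param tax taxonomy data.frame.
#' @param sample sample name.
#' @return A [TaxProfile-class]; with zero classified reads the profile is
#'   empty.
#' @export
taxProfile <- function(assignments, tax, sample = "sample") {
  validateTaxonomy(tax)
  assignments <- assignments[!is.na(assignments)]
  total <- length(assignments)
  if (total == 0) {
    return(methods::new("TaxProfile", sample = sample,
      clades = data.frame(taxon_id = character(), name = character(),
                          rank = character(), clade_count = integer(),
                          abundance = numeric(), stringsAsFactors = FALSE),
      totalClassified = 0L))
  }
  direct <- setNames(integer(nrow(tax)), tax$taxon_id)
  tb <- table(assignments)
  direct[names(tb)] <- as.integer(tb)
  # accumulate direct counts up the tree, deepest ranks first
  clade <- direct
  ord <- order(match(tax$rank, .RANKS), decreasing = TRUE)
  for (i in ord) {
    id <- tax$taxon_id[i]; p <- tax$parent_id[i]
    if (p != id) clade[p] <- clade[p] + clade[id]
  }
  keep <- clade > 0
  clades <- data.frame(taxon_id = tax$taxon_id[keep],
                       name = tax$name[keep],
                       rank = tax$rank[keep],
                       clade_count = as.integer(clade[keep]),
                       abundance = 100 * clade[keep] / total,
                       stringsAsFactors = FALSE)
  rownames(clades) <- NULL
  methods::new("TaxProfile", sample = sample, clades = clades,
               totalClassified = total)
}

# ---- mpa text format -------------------------------------------------------

.lineage <- function(tax, id) {
  parent <- setNames(tax$parent_id, tax$taxon_id)
  name <- setNames(tax$name, tax$taxon_id)
  rank <- setNames(tax$rank, tax$taxon_id)
  path <- id
  while (parent[[id]] != id) { id <- parent[[id]]; path <- c(id, path) }
  paste0(.RANK_PREFIX[rank[path]], gsub("\\s+", "_", name[path]),
         collapse = "|")
}

#' mpa lines for a taxonomic profile
#'
#' One line per clade with a nonzero count: the full lineage joined by `|`
#' with rank prefixes (`k__`, `p__`, ..., `s__`), a TAB, then the rank-level
#' relative abundance with 5 decimal places.
#'
#' @param profile a [TaxProfile-class].
#' @param tax the taxonomy data.frame the profile was computed against
#'   (provides the full lineage of each clade).
#' @param path output file path.
#' @return `writeMpa` returns `path` invisibly.
#' @export
writeMpa <- function(profile, tax, path) {
  cl <- profile@clades
  tab <- data.frame(
    lineage = vapply(cl$taxon_id, function(id) .lineage(tax, id), character(1)),
    abundance = cl$abundance, stringsAsFactors = FALSE)
  writeMpaTable(tab, path)
}

#' Expand species abundances into a full mpa table
#'
#' @param ab named numeric vector of species abundances in percent (names are
#'   species names as in the taxonomy).
#' @param tax taxonomy data.frame.
#' @return data.frame with `lineage`, `rank`, `name`, `abundance` covering
#'   every ancestor clade (abundance of a clade = sum of its species).
#' @export
mpaFromSpeciesAbundance <- function(ab, tax) {
  spRow <- tax[tax$rank == "species", , drop = FALSE]
  id <- spRow$taxon_id[match(names(ab), spRow$name)]
  if (anyNA(id)) stop("unknown species name(s): ",
                      paste(names(ab)[is.na(id)], collapse = ", "))
  clade <- setNames(numeric(nrow(tax)), tax$taxon_id)
  clade[id] <- ab
  ord <- order(match(tax$rank, .RANKS), decreasing = TRUE)
  for (i in ord) {
    tid <- tax$taxon_id[i]; p <- tax$parent_id[i]
    if (p != tid) clade[p] <- clade[p] + clade[tid]
  }
  keep <- clade > 0
  out <- data.frame(
    lineage = vapply(tax$taxon_id[keep], function(x) .lineage(tax, x),
                     character(1)),
    rank = tax$rank[keep],
    name = tax$name[keep],
    abundance = unname(clade[keep]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read an mpa table
#'
#' @param tab data.frame with `lineage` and `abundance` columns.
#' @param path file path.
#' @return `writeMpaTable` returns `path` invisibly; `readMpa` returns a
#'   data.frame with `lineage`, `rank`, `name`, `abundance`.
#' @export
writeMpaTable <- function(tab, path) {
  writeLines(sprintf("%s\t%.5f", tab$lineage, tab$abundance), path)
  invisible(path)
}

#' @rdname writeMpaTable
#' @export
readMpa <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lineage <- vapply(parts, `[[`, character(1), 1)
  abundance <- as.numeric(vapply(parts, `[[`, character(1), 2))
  leaf <- vapply(strsplit(lineage, "|", fixed = TRUE),
                 function(x) x[[length(x)]], character(1))
  prefix <- substr(leaf, 1, 3)
  rank <- names(.RANK_PREFIX)[match(prefix, .RANK_PREFIX)]
  data.frame(lineage = lineage, rank = rank,
             name = substr(leaf, 4, nchar(leaf)),
             abundance = abundance, stringsAsFactors = FALSE)
}

#' Species-level abundance matrix from profiles
#'
#' @param profiles a named list of [TaxProfile-class] objects, or a named
#'   character vector of mpa file paths.
#' @param rank taxonomic rank to extract; default "species".
#' @return Numeric matrix (taxa names x samples) of percent abundances;
#'   absent taxa are 0.
#' @export
abundanceMatrix <- function(profiles, rank = "species") {
  rank <- match.arg(rank, .RANKS)
  if (is.character(profiles)) {
    tabs <- lapply(profiles, function(p) {
      m <- readMpa(p)
      m <- m[m$rank == rank, , drop = FALSE]
      setNames(m$abundance, m$name)
    })
  } else {
    tabs <- lapply(profiles, abundanceAt, rank = rank)
  }
  taxa <- sort(unique(unlist(lapply(tabs, names))))
  m <- matrix(0, length(taxa), length(tabs),
              dimnames = list(taxa, names(profiles)))
  for (j in seq_along(tabs)) m[names(tabs[[j]]), j] <- tabs[[j]]
  m
}
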