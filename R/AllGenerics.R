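#' @name accessors
#' @title Accessors for fecoduo S4 classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param x an object.
#' @return The slot contents.
NULL

#' @rdname accessors
#' @export
setGeneric("precursorSequences", function(x) standardGeneric("precursorSequences"))
#' @rdname accessors
#' @export
setMethod("precursorSequences", "ReferenceBundle", function(x) x@precursors)

#' @rdname accessors
#' @export
setGeneric("armAnnotations", function(x) standardGeneric("armAnnotations"))
#' @rdname accessors
#' @export
setMethod("armAnnotations", "ReferenceBundle", function(x) x@arms)

#' @rdname accessors
#' @export
setGeneric("sncrnaSequences", function(x) standardGeneric("sncrnaSequences"))
#' @rdname accessors
#' @export
setMethod("sncrnaSequences", "ReferenceBundle", function(x) x@sncrnas)

#' @rdname accessors
#' @export
setGeneric("hostGenome", function(x) standardGeneric("hostGenome"))
#' @rdname accessors
#' @export
setMethod("hostGenome", "ReferenceBundle", function(x) x@hostGenome)

#' @rdname accessors
#' @export
setGeneric("dietSequences", function(x) standardGeneric("dietSequences"))
#' @rdname accessors
#' @export
setMethod("dietSequences", "ReferenceBundle", function(x) x@dietMirnas)

#' @rdname accessors
#' @export
setGeneric("speciesGenomes", function(x) standardGeneric("speciesGenomes"))
#' @rdname accessors
#' @export
setMethod("speciesGenomes", "ReferenceBundle", function(x) x@genomes)

#' @rdname accessors
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))
#' @rdname accessors
#' @export
setMethod("taxonomyTable", "ReferenceBundle", function(x) x@taxonomy)
#' @rdname accessors
#' @export
setMethod("taxonomyTable", "KmerLCADB", function(x) x@taxonomy)

#' @rdname accessors
#' @export
setGeneric("bsrnaAnnotations", function(x) standardGeneric("bsrnaAnnotations"))
#' @rdname accessors
#' @export
setMethod("bsrnaAnnotations", "ReferenceBundle", function(x) x@bsrnaAnnotations)

#' @rdname accessors
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))
#' @rdname accessors
#' @export
setMethod("kmerSize", "KmerLCADB", function(x) x@k)

#' @rdname accessors
#' @export
setGeneric("kmerMap", function(x) standardGeneric("kmerMap"))
#' @rdname accessors
#' @export
setMethod("kmerMap", "KmerLCADB", function(x)
  data.frame(kmer = x@kmer, taxon_id = x@taxon, stringsAsFactors = FALSE))

#' @rdname accessors
#' @export
setGeneric("cladeTable", function(x) standardGeneric("cladeTable"))
#' @rdname accessors
#' @export
setMethod("cladeTable", "TaxProfile", function(x) x@clades)

#' @rdname accessors
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))
#' @rdname accessors
#' @export
setMethod("sampleName", "TaxProfile", function(x) x@sample)
#' @rdname accessors
#' @export
setMethod("sampleName", "TriageResult", function(x) x@sample)

#' @rdname accessors
#' @export
setGeneric("totalClassified", function(x) standardGeneric("totalClassified"))
#' @rdname accessors
#' @export
setMethod("totalClassified", "TaxProfile", function(x) x@totalClassified)

#' Relative abundances at one taxonomic rank
#'
#' @param x a [TaxProfile-class].
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return Named numeric vector of percent abundances (names are taxon names).
#' @export
setGeneric("abundanceAt", function(x, rank) standardGeneric("abundanceAt"))
#' @rdname abundanceAt
#' @export
setMethod("abundanceAt", "TaxProfile", function(x, rank) {
  rank <- match.arg(rank, .RANKS)
  cl <- x@clades[x@clades$rank == rank, , drop = FALSE]
  setNames(cl$abundance, cl$name)
})

#' @rdname accessors
#' @export
setGeneric("triageAssignments", function(x) standardGeneric("triageAssignments"))
#' @rdname accessors
#' @export
setMethod("triageAssignments", "TriageResult", function(x) x@assignments)

#' @rdname accessors
#' @export
setGeneric("triageCounts", function(x) standardGeneric("triageCounts"))
#' @rdname accessors
#' @export
setMethod("triageCounts", "TriageResult", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("triageFractions", function(x) standardGeneric("triageFractions"))
#' @rdname accessors
#' @export
setMethod("triageFractions", "TriageResult", function(x) x@fractions)

#' @rdname accessors
#' @export
setGeneric("poolReadIds", function(x, class) standardGeneric("poolReadIds"))
#' @rdname accessors
#' @param class one of the four triage classes.
#' @export
setMethod("poolReadIds", "TriageResult", function(x, class) {
  class <- match.arg(class, .CLASSES)
  x@assignments$read_id[x@assignments$class == class]
})

#' @rdname accessors
#' @export
setGeneric("nrEntries", function(x) standardGeneric("nrEntries"))
#' @rdname accessors
#' @export
setMethod("nrEntries", "NonredundantSRNASet", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("nrMembers", function(x) standardGeneric("nrMembers"))
#' @rdname accessors
#' @export
setMethod("nrMembers", "NonredundantSRNASet", function(x) x@members)

setMethod("show", "ReferenceBundle", function(object) {
  cat("ReferenceBundle\n")
  cat(sprintf("  %d precursors (%d arm-annotated), %d sncRNAs, %d diet miRNAs\n",
              length(object@precursors),
              sum(!is.na(object@arms$arm5_start)),
              length(object@sncrnas), length(object@dietMirnas)))
  cat(sprintf("  host genome: %d bp; %d species genomes (%s bp total)\n",
              length(object@hostGenome), length(object@genomes),
              format(sum(Biostrings::width(object@genomes)), big.mark = ",")))
  cat(sprintf("  taxonomy: %d nodes; %d bsRNA annotations\n",
              nrow(object@taxonomy), nrow(object@bsrnaAnnotations)))
})

setMethod("show", "KmerLCADB", function(object) {
  cat(sprintf("KmerLCADB: %s canonical %d-mers over %d taxa\n",
              format(length(object@kmer), big.mark = ","), object@k,
              nrow(object@taxonomy)))
})

setMethod("show", "TaxProfile", function(object) {
  cat(sprintf("TaxProfile for sample %s: %d classified reads, %d clades\n",
              object@sample, object@totalClassified, nrow(object@clades)))
  sp <- object@clades[object@clades$rank == "species", , drop = FALSE]
  if (nrow(sp)) {
    sp <- sp[order(-sp$abundance), , drop = FALSE]
    top <- head(sp, 3)
    cat("  top species:",
        paste(sprintf("%s (%.2f%%)", top$name, top$abundance), collapse = ", "),
        "\n")
  }
})

setMethod("show", "TriageResult", function(object) {
  cat(sprintf("TriageResult for sample %s (%d reads)\n", object@sample,
              sum(object@counts)))
  for (cl in .CLASSES)
    cat(sprintf("  %-20s %8d (%5.1f%%)\n", cl, object@counts[[cl]],
                100 * object@fractions[[cl]]))
})

setMethod("show", "NonredundantSRNASet", function(object) {
  cat(sprintf("NonredundantSRNASet: %d entries from %d member annotations\n",
              nrow(object@entries), nrow(object@members)))
})
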