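# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixtureBundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- generateReferenceBundle(bundleConfig(), seed = 7)
  .fixtures$bundle
}

smallBundleConfig <- function(...) {
  bundleConfig(n_precursors = 20L, n_sncrnas = 12L, host_genome_length = 30000L,
               n_diet_mirnas = 10L, n_species = 4L, genome_length = 12000L,
               n_bsrna_per_species = 5L, ...)
}

fixtureSmallBundle <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- generateReferenceBundle(smallBundleConfig(), seed = 11)
  .fixtures$small
}

fixtureSmallCohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generateCohort(
      fixtureSmallBundle(),
      cohortConfig(group_sizes = c(healthy = 3L, adenoma = 0L, carcinoma = 3L),
                   reads_per_sample = 6000L),
      seed = 13)
  }
  .fixtures$cohort
}

# hand-built seven-rank taxonomy: 2 phyla, 2 genera, 3 species
# (sA, sB share genus gAB; sC sits alone under the other phylum)
tinyTax <- function() {
  data.frame(
    taxon_id  = c("root", "p1", "c1", "o1", "f1", "gAB", "sA", "sB",
                  "p2", "c2", "o2", "f2", "gC", "sC"),
    name      = c("Bacteria", "PhyA", "ClaA", "OrdA", "FamA", "GenAB",
                  "SpecA", "SpecB", "PhyB", "ClaB", "OrdB", "FamB",
                  "GenC", "SpecC"),
    rank      = c("kingdom", "phylum", "class", "order", "family", "genus",
                  "species", "species", "phylum", "class", "order", "family",
                  "genus", "species"),
    parent_id = c("root", "root", "p1", "c1", "o1", "f1", "gAB", "gAB",
                  "root", "p2", "c2", "o2", "f2", "gC"),
    stringsAsFactors = FALSE)
}

randSeqChr <- function(n, seed = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# inject k substitutions at distinct positions
mutateSeq <- function(seq, positions) {
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  ch <- strsplit(seq, "")[[1]]
  ch[positions] <- swap[ch[positions]]
  paste(ch, collapse = "")
}

TEST_ADAPTER <- "AGATCGGAAGAGCACACGTCT"
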