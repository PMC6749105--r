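Package: fecoduo
Title: Integrated Analysis of Stool Small RNA-Seq and Metagenomic Taxonomic Profiles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the combined analysis of stool small RNA sequencing and
    shotgun metagenomic taxonomic profiles. Reads are triaged hierarchically
    (human small RNA annotations, human genome, dietary miRNAs, microbial
    candidates), mature miRNAs are quantified from precursor hairpins by
    knowledge-based and position-based rules, candidate microbial reads are
    classified with a k-mer lowest-common-ancestor engine into MetaPhlAn-style
    (mpa) relative-abundance profiles, and bacterial small RNA annotations are
    collapsed to a nonredundant set and quantified. Downstream statistics cover
    negative-binomial likelihood-ratio differential expression with covariates,
    Wilcoxon differential abundance, Pearson concordance between DNA- and
    RNA-derived profiles, transcription-rate ratios, and a leakage-safe
    repeated cross-validated Random Forest classification protocol. A
    synthetic-data module generates reference bundles and cohorts with known
    ground truth so that every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    ranger
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    DESeq2,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
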