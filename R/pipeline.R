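#' Default pipeline configuration
#'
#' One declarative object drives the whole run: either a synthetic mode
#' (bundle + cohort generated in memory with known ground truth) or a file
#' mode (FASTA/TSV reference bundle directory, per-sample FASTQ, metadata
#' TSV, per-sample DNA profiles in mpa format). Every threshold named by the
#' analysis modules is exposed here.
#'
#' @param seed global RNG seed.
#' @param simulate generate bundle and cohort in memory (TRUE) or read the
#'   `input` paths (FALSE).
#' @param bundle,cohort configurations for [generateReferenceBundle()] /
#'   [generateCohort()] (synthetic mode).
#' @param input list of paths (file mode): `bundle_dir`, `fastq` (named
#'   vector of per-sample FASTQ paths), `metadata` (TSV), `dna_mpa` (named
#'   vector of per-sample mpa paths).
#' @param preprocess adapter-trimming and length-filter settings.
#' @param align maximum mismatch count for the alignment passes.
#' @param tax k-mer size and minimum classifiable read length.
#' @param bsrna nonredundant-set thresholds.
#' @param de,da,concordance statistical thresholds (DE filter, abundance
#'   filters, correlation threshold).
#' @param ml Random Forest protocol settings; `categories` may be a preset
#'   name ("all", "paper14") or a list of type subsets.
#' @param out_dir output directory (required by [runPipeline()]).
#' @return Nested configuration list.
#' @export
pipelineConfig <- function(seed = 1L,
                           simulate = TRUE,
                           bundle = bundleConfig(),
                           cohort = cohortConfig(),
                           input = list(bundle_dir = NULL, fastq = NULL,
                                        metadata = NULL, dna_mpa = NULL),
                           preprocess = list(max_error_rate = 0.15,
                                             min_overlap = 3L,
                                             min_length = 14L,
                                             trim_first = TRUE),
                           align = list(max_mismatches = 2L),
                           tax = list(k = 31L, min_classify_length = 31L),
                           bsrna = list(min_species_abundance = 0.01,
                                        max_length = 80L),
                           de = list(alpha = 0.05, min_group_median = 20),
                           da = list(min_mean_abundance = 0.1, alpha = 0.05),
                           concordance = list(min_abundance = 0.1,
                                              min_r = 0.6, alpha = 0.05),
                           ml = list(enabled = TRUE,
                                     categories = list(
                                       "hsa_miRNA", "bDNA",
                                       c("hsa_miRNA", "bDNA", "bsRNA")),
                                     folds = 5L, iterations = 4L,
                                     num_trees = 200L),
                           out_dir = NULL) {
  as.list(environment())
}

.contrasts <- list(c("healthy", "adenoma"), c("adenoma", "carcinoma"),
                   c("healthy", "carcinoma"))

.wt <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — preprocessing, hierarchical triage, mature
#' miRNA / sncRNA quantification, k-mer LCA classification into mpa
#' profiles, nonredundant bsRNA quantification, differential expression and
#' abundance statistics, DNA-RNA concordance and transcription-rate
#' integration, and the Random Forest experiment grid — and writes every
#' artifact plus a provenance log into `config$out_dir`. Re-running with the
#' same config and seed reproduces all numeric outputs bit-identically.
#'
#' @param config see [pipelineConfig()].
#' @return Invisibly, a list with all in-memory results (`bundle`, `cohort`
#'   or loaded inputs, `triage`, count matrices, profiles, statistics, `ml`).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.null(config$out_dir)) stop("config$out_dir must be set")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "rna_mpa"), showWarnings = FALSE)
  log <- function(...) message("[fecoduo] ", sprintf(...))

  # ---- stage 0: inputs
  if (isTRUE(config$simulate)) {
    log("simulating reference bundle and cohort (seed %d)", config$seed)
    bundle <- generateReferenceBundle(config$bundle, seed = config$seed)
    cohort <- generateCohort(bundle, config$cohort, seed = config$seed + 1L)
    meta <- cohort$metadata
    readsBySample <- cohort$reads
    dnaSpecies <- cohort$dnaProfiles
    adapter <- cohort$config$adapter
  } else {
    inp <- config$input
    for (p in c(inp$bundle_dir, inp$metadata, inp$fastq, inp$dna_mpa))
      if (!file.exists(p)) stop("input path does not exist: ", p)
    bundle <- readBundle(inp$bundle_dir)
    meta <- read.table(inp$metadata, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
    readsBySample <- lapply(inp$fastq, readFastq)
    names(readsBySample) <- names(inp$fastq)
    dnaSpecies <- abundanceMatrix(inp$dna_mpa, rank = "species")
    cohort <- NULL
    adapter <- config$preprocess$adapter
    if (is.null(adapter)) stop("preprocess$adapter is required in file mode")
  }
  samples <- meta$sample_id
  tax <- bundle@taxonomy
  spName <- setNames(tax$name[tax$rank == "species"],
                     tax$taxon_id[tax$rank == "species"])

  # ---- stages 1-2: preprocess + triage, per sample
  pp <- config$preprocess
  mmax <- config$align$max_mismatches
  prepReports <- list(); triage <- list()
  mirnaCols <- list(); sncCols <- list(); rnaProfiles <- list()
  bsrnaCols <- list(); poolBySample <- list()

  db <- buildKmerLcaDb(speciesGenomes(bundle), tax, k = config$tax$k)
  log("k-mer LCA database: %d %d-mers", length(db@kmer), db@k)

  dnaById <- dnaSpecies
  rownames(dnaById) <- names(spName)[match(rownames(dnaSpecies), spName)]
  nrset <- collapseAnnotations(bundle@bsrnaAnnotations, dnaById,
                               config$bsrna$min_species_abundance,
                               config$bsrna$max_length)
  log("nonredundant bsRNA set: %d entries", nrow(nrset@entries))

  rawCounts <- integer(0)
  for (s in samples) {
    raw <- readsBySample[[s]]
    rawCounts[s] <- nrow(raw)
    prep <- preprocessReads(raw, adapter, pp$max_error_rate, pp$min_overlap,
                            pp$min_length, pp$trim_first)
    prepReports[[s]] <- cbind(sample = s, prep$report)
    tri <- triageReads(prep$reads, bundle, mmax, sample = s)
    # read conservation across preprocessing and triage
    stopifnot(sum(triageCounts(tri)) + prep$report$n_discarded_short ==
                nrow(raw))
    triage[[s]] <- tri

    # partition stage-1 reads by their best hit so each read counts once
    # across the miRNA and sncRNA matrices
    best1 <- .bestHits(tri@srnaAlignments)
    preIds <- names(precursorSequences(bundle))
    sncIds <- names(sncrnaSequences(bundle))
    a1 <- tri@srnaAlignments
    mirAln <- a1[a1$read_id %in% best1$read_id[best1$ref_id %in% preIds] &
                   a1$ref_id %in% preIds, , drop = FALSE]
    sncAln <- a1[a1$read_id %in% best1$read_id[best1$ref_id %in% sncIds] &
                   a1$ref_id %in% sncIds, , drop = FALSE]
    mirnaCols[[s]] <- countsOf(quantifyMirna(mirAln, bundle, s))[, 1]
    sncCols[[s]] <- countsOf(quantifyAnnotationCounts(sncAln, sncIds, s))[, 1]

    poolIds <- poolReadIds(tri, "candidate_microbial")
    pool <- setNames(prep$reads$seq, prep$reads$read_id)[poolIds]
    poolBySample[[s]] <- pool
    cls <- classifyReads(pool, db, config$tax$min_classify_length)
    rnaProfiles[[s]] <- taxProfile(cls, tax, sample = s)
    writeMpa(rnaProfiles[[s]], tax, file.path(out, "rna_mpa", paste0(s, ".mpa")))
    bsrnaCols[[s]] <- countsOf(quantifyBsrna(pool, nrset, mmax, s))[, 1]
    log("sample %s: %d reads, %.1f%% srna / %.1f%% genome / %.1f%% candidate",
        s, nrow(raw), 100 * triageFractions(tri)[["hsa_srna"]],
        100 * triageFractions(tri)[["hsa_genome"]],
        100 * triageFractions(tri)[["candidate_microbial"]])
  }

  triSummary <- do.call(rbind, lapply(triage, function(t)
    data.frame(sample = sampleName(t), t(triageFractions(t)),
               check.names = FALSE)))
  .wt(triSummary, file.path(out, "triage_summary.tsv"))
  .wt(do.call(rbind, prepReports), file.path(out, "preprocess_report.tsv"))

  mirnaFeats <- mirnaFeatureNames(bundle)
  mirnaSE <- .countSE(.bindCounts(mirnaCols, mirnaFeats, samples))
  sncSE <- .countSE(.bindCounts(sncCols, names(sncrnaSequences(bundle)), samples),
                    rowData = data.frame(biotype = unname(bundle@sncrnaBiotype),
                                         row.names = names(bundle@sncrnaBiotype)))
  bsrnaSE <- .countSE(.bindCounts(bsrnaCols, nrset@entries$entry_id, samples))
  .wt(data.frame(feature = rownames(countsOf(mirnaSE)), countsOf(mirnaSE),
                 check.names = FALSE), file.path(out, "counts_mirna.tsv"))
  .wt(data.frame(feature = rownames(countsOf(sncSE)), countsOf(sncSE),
                 check.names = FALSE), file.path(out, "counts_sncrna.tsv"))
  .wt(data.frame(feature = rownames(countsOf(bsrnaSE)), countsOf(bsrnaSE),
                 check.names = FALSE), file.path(out, "counts_bsrna.tsv"))
  .wt(nrset@members, file.path(out, "bsrna_nr_members.tsv"))

  rnaSpecies <- abundanceMatrix(rnaProfiles, rank = "species")

  # ---- stage 3: statistics
  deAll <- list()
  for (ctr in .contrasts) {
    nm <- paste(ctr, collapse = "_vs_")
    for (ty in c("mirna", "sncrna", "bsrna")) {
      cnt <- switch(ty, mirna = mirnaSE, sncrna = sncSE, bsrna = bsrnaSE)
      de <- nbLrtDe(cnt, meta, ctr)
      flt <- filterDe(de, cnt, meta, config$de$alpha,
                      config$de$min_group_median)
      deAll[[paste(ty, nm, sep = "_")]] <- list(all = de, filtered = flt)
      .wt(de, file.path(out, sprintf("de_%s_%s.tsv", ty, nm)))
      .wt(flt, file.path(out, sprintf("de_%s_%s_filtered.tsv", ty, nm)))
    }
  }
  daAll <- list()
  for (ctr in .contrasts) {
    nm <- paste(ctr, collapse = "_vs_")
    da <- wilcoxonDa(dnaSpecies, meta, ctr, config$da$min_mean_abundance)
    daAll[[nm]] <- da
    .wt(da, file.path(out, sprintf("da_dna_species_%s.tsv", nm)))
  }

  # ---- stage 4: DNA-RNA integration
  conc <- list()
  for (rk in c("phylum", "class", "order", "family", "genus", "species")) {
    dnaRank <- .rollupRank(dnaSpecies, tax, rk)
    rnaRank <- abundanceMatrix(rnaProfiles, rank = rk)
    shared <- intersect(rownames(dnaRank), rownames(rnaRank))
    if (!length(shared)) next
    rec <- pearsonScreen(rnaRank[shared, samples, drop = FALSE],
                         dnaRank[shared, samples, drop = FALSE])
    rec$rank <- rk
    conc[[rk]] <- rec
  }
  concordance <- do.call(rbind, conc)
  rownames(concordance) <- NULL
  .wt(concordance, file.path(out, "concordance.tsv"))
  spRec <- concordance[concordance$rank == "species", , drop = FALSE]
  selected <- selectCorrelatedSpecies(spRec, dnaSpecies, meta,
                                      config$concordance$min_abundance,
                                      config$concordance$min_r,
                                      config$concordance$alpha)
  writeLines(selected, file.path(out, "correlated_species.txt"))

  rates <- transcriptionRate(rnaSpecies, dnaSpecies)
  rateSummary <- summarizeTranscriptionRates(rates)
  .wt(rates, file.path(out, "transcription_rates.tsv"))
  .wt(rateSummary, file.path(out, "transcription_rate_summary.tsv"))

  # miRNA correlation screen against the most DNA-abundant species
  target <- rownames(dnaSpecies)[which.max(rowMeans(dnaSpecies))]
  mirLog <- assembleFeatures(list(hsa_miRNA = mirnaSE), "hsa_miRNA")
  mirCor <- pearsonScreen(t(mirLog), dnaSpecies[target, rownames(mirLog)])
  .wt(cbind(target_species = target, mirCor),
      file.path(out, "mirna_species_correlation.tsv"))

  # ---- stage 5: classification protocol
  ml <- NULL
  if (isTRUE(config$ml$enabled)) {
    profiles <- list(bDNA = dnaSpecies, bsRNA = rnaSpecies,
                     hsa_miRNA = countsOf(mirnaSE),
                     hsa_sncRNA = countsOf(sncSE))
    ml <- runExperimentGrid(profiles, meta,
                            categories = config$ml$categories,
                            folds = config$ml$folds,
                            iterations = config$ml$iterations,
                            seed = config$seed,
                            num_trees = config$ml$num_trees)
    .wt(ml$summary, file.path(out, "ml_summary.tsv"))
  }

  # ---- provenance (hash excludes machine-local paths so identical analyses
  # in different directories fingerprint identically)
  cfgCore <- config
  cfgCore$out_dir <- NULL
  cfgCore$input <- NULL
  cfgHash <- fnvHash(paste(deparse(cfgCore), collapse = "\n"))
  writeLines(c(
    sprintf("fecoduo version: %s", as.character(packageVersion("fecoduo"))),
    sprintf("R version: %s", R.version.string),
    sprintf("seed: %d", config$seed),
    sprintf("config hash (fnv1a64): %s", cfgHash),
    sprintf("samples: %d", length(samples)),
    sprintf("raw reads: %s", paste(rawCounts, collapse = ","))),
    file.path(out, "provenance.txt"))
  .wt(meta, file.path(out, "metadata.tsv"))

  invisible(list(bundle = bundle, cohort = cohort, metadata = meta,
                 triage = triage, mirna = mirnaSE, sncrna = sncSE,
                 bsrna = bsrnaSE, nrset = nrset,
                 rnaProfiles = rnaProfiles, rnaSpecies = rnaSpecies,
                 dnaSpecies = dnaSpecies, de = deAll, da = daAll,
                 concordance = concordance, correlatedSpecies = selected,
                 transcriptionRates = rates,
                 transcriptionRateSummary = rateSummary, ml = ml,
                 out_dir = out))
}

# roll a species-by-sample percent matrix up to a higher rank via the taxonomy
.rollupRank <- function(speciesAb, tax, rank) {
  if (rank == "species") return(speciesAb)
  sp <- tax[tax$rank == "species", , drop = FALSE]
  parent <- setNames(tax$parent_id, tax$taxon_id)
  rankOf <- setNames(tax$rank, tax$taxon_id)
  nameOf <- setNames(tax$name, tax$taxon_id)
  anc <- vapply(sp$taxon_id, function(id) {
    while (rankOf[[id]] != rank && parent[[id]] != id) id <- parent[[id]]
    if (rankOf[[id]] == rank) nameOf[[id]] else NA_character_
  }, character(1))
  names(anc) <- sp$name
  groups <- anc[rownames(speciesAb)]
  keep <- !is.na(groups)
  rowsum(speciesAb[keep, , drop = FALSE], groups[keep])
}
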