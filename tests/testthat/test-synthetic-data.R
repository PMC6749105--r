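test_that("bundle generation is deterministic for a fixed config and seed", {
  b1 <- generateReferenceBundle(smallBundleConfig(), seed = 7)
  b2 <- generateReferenceBundle(smallBundleConfig(), seed = 7)
  expect_identical(as.character(precursorSequences(b1)),
                   as.character(precursorSequences(b2)))
  expect_identical(as.character(hostGenome(b1)), as.character(hostGenome(b2)))
  expect_identical(as.character(speciesGenomes(b1)),
                   as.character(speciesGenomes(b2)))
  expect_identical(armAnnotations(b1), armAnnotations(b2))
  b3 <- generateReferenceBundle(smallBundleConfig(), seed = 8)
  expect_false(identical(as.character(hostGenome(b1)),
                         as.character(hostGenome(b3))))
})

test_that("bundle satisfies its structural invariants", {
  b <- fixtureSmallBundle()
  expect_true(validObject(b))
  tax <- taxonomyTable(b)
  expect_equal(sum(tax$taxon_id == tax$parent_id), 1) # single root
  # a configurable fraction of precursors carry both arms, the rest none
  arms <- armAnnotations(b)
  both <- !is.na(arms$arm5_start) & !is.na(arms$arm3_start)
  none <- is.na(arms$arm5_start) & is.na(arms$arm3_start)
  expect_true(all(both | none))
  expect_equal(sum(both), round(0.7 * 20))
  # arm intervals are inside the hairpin and ordered
  w <- Biostrings::width(precursorSequences(b))[both]
  expect_true(all(arms$arm5_end[both] <= arms$arm3_start[both]))
  expect_true(all(arms$arm3_end[both] <= w))
  # >= 2 bsRNA sequences shared across distinct species
  ann <- bsrnaAnnotations(b)
  shared <- ann$sequence[duplicated(ann$sequence)]
  expect_gte(length(unique(shared)), 2)
  for (s in unique(shared))
    expect_gte(length(unique(ann$species_id[ann$sequence == s])), 2)
})

test_that("taxonomy shape: n_species = 3 gives one root and 3 species leaves", {
  b <- generateReferenceBundle(bundleConfig(n_species = 3L), seed = 2)
  tax <- taxonomyTable(b)
  expect_equal(sum(tax$taxon_id == tax$parent_id), 1)
  sp <- tax$taxon_id[tax$rank == "species"]
  expect_length(sp, 3)
  expect_false(any(sp %in% tax$parent_id[tax$parent_id != tax$taxon_id]))
})

test_that("sibling species share the configured fraction of 31-mers", {
  b <- generateReferenceBundle(
    bundleConfig(n_species = 2L, sibling_pair = TRUE,
                 sibling_shared_kmer_frac = 0.5, n_shared_bsrna = 0L,
                 genome_length = 20000L),
    seed = 5)
  g <- as.character(speciesGenomes(b))
  k1 <- unique(oracleCanonical(oracleKmers(g[[1]], 31)))
  k2 <- unique(oracleCanonical(oracleKmers(g[[2]], 31)))
  shared <- length(intersect(k1, k2)) / length(k1)
  expect_gt(shared, 0.45)
  expect_lt(shared, 0.55)
})

test_that("divergent species genomes share almost no 31-mers", {
  b <- fixtureSmallBundle()
  g <- as.character(speciesGenomes(b))
  k1 <- unique(oracleCanonical(oracleKmers(g[[1]], 31)))
  k3 <- unique(oracleCanonical(oracleKmers(g[[3]], 31)))
  expect_lt(length(intersect(k1, k3)) / length(k1), 0.1)
})

test_that("cohort generation is deterministic and validates fractions", {
  b <- fixtureSmallBundle()
  cfg <- cohortConfig(group_sizes = c(healthy = 1L, adenoma = 0L,
                                      carcinoma = 1L),
                      reads_per_sample = 1000L)
  c1 <- generateCohort(b, cfg, seed = 4)
  c2 <- generateCohort(b, cfg, seed = 4)
  expect_identical(c1$reads, c2$reads)
  expect_identical(c1$dnaProfiles, c2$dnaProfiles)
  bad <- cfg; bad$provenance["junk"] <- 0.5
  expect_error(generateCohort(b, bad, seed = 1), "sum to 1")
  expect_error(cohortConfig(provenance = c(human_srna = 0.5, human_genome = 0.5,
                                           diet = 0, bacterial = 0.5,
                                           junk = 0)), "sum to 1")
})

test_that("truth-table class counts match the configured multinomial", {
  b <- fixtureSmallBundle()
  co <- generateCohort(b, cohortConfig(
    group_sizes = c(healthy = 1L, adenoma = 0L, carcinoma = 0L),
    reads_per_sample = 10000L), seed = 9)
  tab <- table(co$truth$classes[[1]]$class)
  expected <- co$config$provenance * 10000
  for (cl in names(expected)) {
    got <- if (cl %in% names(tab)) tab[[cl]] else 0
    # within +-2% of total and 3 sigma of the binomial sd
    expect_lt(abs(got - expected[[cl]]), max(200, 3 * sqrt(expected[[cl]])))
  }
})

test_that("zero-noise DNA profiles equal true proportions exactly (x100)", {
  b <- fixtureSmallBundle()
  co <- generateCohort(b, cohortConfig(
    group_sizes = c(healthy = 2L, adenoma = 0L, carcinoma = 0L),
    reads_per_sample = 500L, dna_noise_sigma = 0), seed = 3)
  expect_equal(co$dnaProfiles, 100 * co$truth$speciesProportions,
               tolerance = 1e-12)
})

test_that("bacterial inserts are single-species genome substrings (no chimeras)", {
  b <- fixtureSmallBundle()
  co <- fixtureSmallCohort()
  tr <- co$truth$classes[[1]]
  reads <- co$reads[[1]]
  bact <- tr[tr$class == "bacterial", ][1:50, ]
  g <- as.character(speciesGenomes(b))
  for (i in seq_len(nrow(bact))) {
    insert <- substr(reads$seq[match(bact$read_id[i], reads$read_id)],
                     1, bact$insert_length[i])
    gen <- g[[bact$source[i]]]
    expect_true(grepl(insert, gen, fixed = TRUE) ||
                  grepl(oracleRevComp(insert), gen, fixed = TRUE))
  }
})

test_that("injected miRNA group effects are recoverable from realized counts", {
  b <- fixtureSmallBundle()
  co <- generateCohort(b, cohortConfig(
    group_sizes = c(healthy = 20L, adenoma = 0L, carcinoma = 20L),
    reads_per_sample = 20000L), seed = 21)
  eff <- co$truth$mirnaEffects
  eff <- eff[eff$group == "carcinoma", ]
  cnt <- co$truth$mirnaCounts
  h <- co$metadata$sample_id[co$metadata$group == "healthy"]
  c2 <- co$metadata$sample_id[co$metadata$group == "carcinoma"]
  for (i in seq_len(nrow(eff))) {
    lr <- log2(mean(cnt[eff$feature[i], c2]) / mean(cnt[eff$feature[i], h]))
    expect_lt(abs(lr - eff$log2fc[i]), 0.5)
  }
})

test_that("cohort serialization writes FASTQ, metadata, mpa and truth", {
  b <- fixtureSmallBundle()
  co <- generateCohort(b, cohortConfig(
    group_sizes = c(healthy = 1L, adenoma = 0L, carcinoma = 1L),
    reads_per_sample = 300L), seed = 2)
  d <- withr::local_tempdir()
  writeCohort(co, d, b)
  expect_true(file.exists(file.path(d, "metadata.tsv")))
  fq <- readFastq(file.path(d, "fastq", "S01.fastq"))
  expect_equal(fq$seq, co$reads[["S01"]]$seq)
  expect_equal(nchar(fq$qual), nchar(fq$seq))
  mpa <- readMpa(file.path(d, "dna_mpa", "S01.mpa"))
  sp <- mpa[mpa$rank == "species", ]
  expect_equal(sort(sp$name),
               sort(rownames(co$dnaProfiles)[co$dnaProfiles[, "S01"] > 0]))
  expect_equal(sum(sp$abundance), 100, tolerance = 1e-3)
})
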