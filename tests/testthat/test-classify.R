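test_that("feature assembly prefixes, transforms, and validates samples", {
  set.seed(61)
  samples <- paste0("S", 1:6)
  mir <- matrix(rpois(30, 40), nrow = 5,
                dimnames = list(paste0("m", 1:5), samples))
  mir[3, ] <- 0L # constant-zero feature is retained
  dna <- matrix(runif(12, 0, 10), nrow = 2,
                dimnames = list(c("spA", "spB"), samples))
  bsr <- matrix(runif(18, 0, 5), nrow = 3,
                dimnames = list(paste0("e", 1:3), samples))
  profiles <- list(hsa_miRNA = mir, bDNA = dna, bsRNA = bsr)

  x <- assembleFeatures(profiles, "hsa_miRNA")
  expect_true(all(startsWith(colnames(x), "hsa_miRNA|")))
  expect_equal(dim(x), c(6, 5))
  expect_true(all(x[, "hsa_miRNA|m3"] == x[1, "hsa_miRNA|m3"]))
  # counts transformed to log10(1 + CPM): bounded by log10(1 + 1e6)
  expect_true(all(x >= 0 & x <= log10(1 + 1e6)))

  x2 <- assembleFeatures(profiles, c("bDNA", "bsRNA"))
  expect_equal(ncol(x2), nrow(dna) + nrow(bsr))
  # abundance types pass through untransformed
  expect_equal(unname(x2[, "bDNA|spA"]), unname(dna["spA", ]))

  short <- profiles
  short$bDNA <- dna[, 1:4]
  expect_error(assembleFeatures(short, c("hsa_miRNA", "bDNA")), "S5")
})

test_that("rank-based AUC matches trapezoidal ROC integration", {
  expect_equal(aucScore(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(aucScore(rep(0.5, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(aucScore(c(0.9, 0.8, 0.85, 0.7),
                        c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(aucScore(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  set.seed(62)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n) # continuous, tie-free
    expect_lt(abs(aucScore(scores, labels) -
                    oracleAucTrapezoid(scores, labels)), 1e-9)
  }
})

test_that("cross-validation yields folds x iterations AUCs and errors on bad strata", {
  set.seed(63)
  n <- 12
  x <- matrix(rnorm(2 * n * 6), nrow = 2 * n,
              dimnames = list(paste0("S", 1:(2 * n)), paste0("F", 1:6)))
  x[(n + 1):(2 * n), 1:2] <- x[(n + 1):(2 * n), 1:2] + 3
  labels <- rep(c("healthy", "carcinoma"), each = n)
  cv <- crossValidate(x, labels, "carcinoma", folds = 4, iterations = 3,
                      seed = 1, num_trees = 60)
  expect_length(cv$auc_per_test, 12)
  expect_true(all(cv$auc_per_test >= 0 & cv$auc_per_test <= 1))
  expect_gt(cv$mean_auc, 0.9)
  # informative features rank at the top
  expect_true(all(startsWith(names(cv$feature_importances)[1:2], "F")))
  expect_setequal(names(cv$feature_importances)[1:2], c("F1", "F2"))
  # a fold cannot miss a class: folds > smallest class size
  expect_error(crossValidate(x, labels, "carcinoma", folds = n + 1,
                             iterations = 1, seed = 1, num_trees = 10),
               "stratification")
  # determinism for a fixed seed
  cv2 <- crossValidate(x, labels, "carcinoma", folds = 4, iterations = 3,
                       seed = 1, num_trees = 60)
  expect_identical(cv$auc_per_test, cv2$auc_per_test)
})

test_that("feature sweep ranks on training folds only and spans the grid", {
  set.seed(64)
  n <- 15
  x <- matrix(rnorm(2 * n * 10), nrow = 2 * n,
              dimnames = list(paste0("S", 1:(2 * n)), paste0("F", 1:10)))
  x[(n + 1):(2 * n), 1] <- x[(n + 1):(2 * n), 1] + 4 # one informative feature
  labels <- rep(c("healthy", "carcinoma"), each = n)
  fs <- featureSweep(x, labels, "carcinoma", grid = c(1, 5, 10), folds = 3,
                     iterations = 2, seed = 2, num_trees = 100,
                     assert_no_leakage = TRUE)
  expect_equal(fs$sweep_curve$n_features, c(1, 5, 10))
  expect_equal(nrow(fs$auc_per_test), 6)
  # the single informative feature carries the signal
  expect_gt(fs$sweep_curve$mean_auc[1], 0.85)
  expect_lt(abs(fs$sweep_curve$mean_auc[1] - fs$sweep_curve$mean_auc[3]), 0.1)
  expect_equal(names(fs$top_feature_frequency)[1], "F1")
})

test_that("the experiment grid enumerates categories x comparisons", {
  expect_length(categoryPresets("all"), 15)
  expect_length(categoryPresets("paper14"), 14)
  expect_false(any(vapply(categoryPresets("paper14"), setequal,
                          logical(1), c("hsa_miRNA", "hsa_sncRNA"))))

  set.seed(65)
  samples <- paste0("S", 1:18)
  meta <- data.frame(sample_id = samples,
                     group = rep(c("healthy", "adenoma", "carcinoma"), each = 6),
                     stringsAsFactors = FALSE)
  mk <- function(nf, count = FALSE) {
    m <- if (count) matrix(rpois(nf * 18, 30), nrow = nf)
         else matrix(runif(nf * 18, 0, 10), nrow = nf)
    dimnames(m) <- list(paste0("f", seq_len(nf)), samples)
    m
  }
  profiles <- list(bDNA = mk(3), bsRNA = mk(3),
                   hsa_miRNA = mk(4, TRUE), hsa_sncRNA = mk(3, TRUE))
  grid <- runExperimentGrid(profiles, meta, categories = "paper14",
                            folds = 2, iterations = 1, seed = 1,
                            num_trees = 10)
  expect_equal(nrow(grid$summary), 42)
  expect_true(all(grid$summary$positive[
    grepl("carcinoma", grid$summary$comparison)] == "carcinoma"))
  expect_true(all(grid$summary$positive[
    grid$summary$comparison == "healthy vs adenoma"] == "adenoma"))

  grid15 <- runExperimentGrid(profiles, meta, categories = "all",
                              folds = 2, iterations = 1, seed = 1,
                              num_trees = 5)
  expect_equal(nrow(grid15$summary), 45)
  one <- runExperimentGrid(profiles, meta, categories = list("bDNA"),
                           comparisons = list(c("healthy", "carcinoma")),
                           folds = 2, iterations = 1, seed = 1, num_trees = 5)
  expect_equal(nrow(one$summary), 1)
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  set.seed(66)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1) # ties included
    ref <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(labels, scores, direction = "<", quiet = TRUE))))
    expect_equal(aucScore(scores, labels), ref, tolerance = 1e-12)
  }
})
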