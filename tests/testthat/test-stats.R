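test_that("size factors follow median-of-ratios with geometric mean 1", {
  m <- matrix(rpois(40, 50) + 1, nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("S", 1:4)))
  # identical columns -> all factors 1
  same <- m; for (j in 2:4) same[, j] <- same[, 1]
  expect_equal(unname(estimateSizeFactors(same)), rep(1, 4))
  # sample B = 2 x sample A featurewise -> factor ratio 2
  two <- cbind(A = m[, 1], B = 2L * m[, 1])
  sf <- estimateSizeFactors(two)
  expect_equal(unname(sf[["B"]] / sf[["A"]]), 2)
  expect_equal(exp(mean(log(sf))), 1)
  # single sample -> factor 1
  expect_equal(unname(estimateSizeFactors(m[, 1, drop = FALSE])), 1)
  # no all-positive feature -> library-size fallback with warning
  z <- m; z[, 1] <- 0L; z[1, 1] <- 5L; z[1, 2:4] <- 0L
  expect_warning(estimateSizeFactors(z), "library-size")
})

test_that("NB-LRT returns a null result for constant features", {
  set.seed(51)
  n <- 6
  meta <- data.frame(sample_id = paste0("S", 1:(2 * n)),
                     group = rep(c("healthy", "carcinoma"), each = n),
                     age = round(runif(2 * n, 40, 80)),
                     gender = sample(c("M", "F"), 2 * n, TRUE))
  cnt <- matrix(7L, nrow = 2, ncol = 2 * n,
                dimnames = list(c("flat", "flat2"), meta$sample_id))
  de <- nbLrtDe(cnt, meta, c("healthy", "carcinoma"))
  expect_true(all(de$lrt_statistic < 1e-6))
  expect_true(all(de$p_value > 0.999))
  expect_true(all(de$bh_adjusted_p >= de$p_value - 1e-12))
})

test_that("NB-LRT detects a strong group effect with covariates", {
  set.seed(52)
  n <- 8
  meta <- data.frame(sample_id = paste0("S", 1:(2 * n)),
                     group = rep(c("healthy", "carcinoma"), each = n),
                     age = round(runif(2 * n, 40, 80)),
                     gender = sample(c("M", "F"), 2 * n, TRUE))
  mu <- rbind(outer(rep(100, 5), ifelse(meta$group == "carcinoma", 4, 1)),
              matrix(100, 45, 2 * n))
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 10), nrow = nrow(mu),
                dimnames = list(paste0("g", seq_len(nrow(mu))), meta$sample_id))
  de <- nbLrtDe(cnt, meta, c("healthy", "carcinoma"))
  expect_true(all(de$bh_adjusted_p[1:5] < 0.01))
  expect_true(all(abs(de$log2_fold_change[1:5] - 2) < 0.8))
  expect_gt(mean(de$p_value[6:50] > 0.05), 0.8)
})

test_that("NB-LRT is approximately invariant to an absorbed rescaling", {
  set.seed(53)
  n <- 8
  meta <- data.frame(sample_id = paste0("S", 1:(2 * n)),
                     group = rep(c("healthy", "carcinoma"), each = n),
                     age = round(runif(2 * n, 40, 80)),
                     gender = sample(c("M", "F"), 2 * n, TRUE))
  cnt <- matrix(rnbinom(60 * 2 * n, mu = 150, size = 5), nrow = 60,
                dimnames = list(paste0("g", 1:60), meta$sample_id))
  de1 <- nbLrtDe(cnt, meta, c("healthy", "carcinoma"))
  cnt2 <- cnt; cnt2[, 2] <- cnt2[, 2] * 3L
  de2 <- nbLrtDe(cnt2, meta, c("healthy", "carcinoma"))
  expect_lt(max(abs(de1$p_value - de2$p_value)), 0.02)
})

test_that("DE filter applies strict thresholds on adjusted p and group medians", {
  meta <- data.frame(sample_id = paste0("S", 1:6),
                     group = rep(c("healthy", "carcinoma"), each = 3))
  cnt <- rbind(lowMed = c(5, 8, 12, 5, 8, 12),
               highA = c(25, 25, 25, 3, 3, 3),
               border = c(20, 20, 20, 20, 20, 20))
  colnames(cnt) <- meta$sample_id
  res <- data.frame(feature_id = rownames(cnt),
                    bh_adjusted_p = c(0.01, 0.01, 0.01))
  kept <- filterDe(res, cnt, meta)
  expect_equal(kept$feature_id, "highA")   # medians {5,8,12} excluded; 20 is not > 20
  res2 <- data.frame(feature_id = "highA", bh_adjusted_p = 0.05)
  expect_equal(nrow(filterDe(res2, cnt, meta)), 0)  # 0.05 exactly -> excluded
})

test_that("Wilcoxon differential abundance matches exact enumeration", {
  meta <- data.frame(sample_id = paste0("S", 1:6),
                     group = rep(c("g1", "g2"), each = 3))
  ab <- rbind(sep = c(1, 2, 3, 4, 5, 6),
              dim = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
              flat = c(2, 2, 2, 2, 2, 2))
  colnames(ab) <- meta$sample_id
  res <- wilcoxonDa(ab, meta, c("g1", "g2"))
  # fully separated 3v3: exact two-sided p = 2/20 = 0.1
  expect_equal(res$p_value[res$taxon == "sep"], 0.1)
  # below the 0.1% abundance filter -> not tested
  expect_false("dim" %in% res$taxon)
  # all-constant taxon -> p = 1
  expect_equal(res$p_value[res$taxon == "flat"], 1)
})

test_that("Wilcoxon exact and approximate paths agree closely at n = 10", {
  set.seed(54)
  meta <- data.frame(sample_id = paste0("S", 1:20),
                     group = rep(c("g1", "g2"), each = 10))
  for (i in 1:20) {
    x <- runif(20, 1, 10) # continuous, no ties
    pe <- wilcox.test(x[1:10], x[11:20], exact = TRUE)$p.value
    pa <- wilcox.test(x[1:10], x[11:20], exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(pe - pa), 0.02)
  }
  # null calibration: median p over many null taxa near 0.5
  ab <- matrix(runif(1000 * 20, 1, 5), nrow = 1000,
               dimnames = list(paste0("t", 1:1000), meta$sample_id))
  res <- wilcoxonDa(ab, meta, c("g1", "g2"))
  expect_gt(median(res$p_value), 0.4)
  expect_lt(median(res$p_value), 0.6)
})

test_that("Pearson screen computes r, t-based p, and flags zero variance", {
  x <- matrix(c(1, 2, 3, 4,
                1, 2, 3, 4,
                5, 5, 5, 5,
                1, 2, 4, 3), nrow = 4, byrow = TRUE,
              dimnames = list(c("id", "neg", "const", "perm"), paste0("S", 1:4)))
  y <- c(1, 2, 3, 4); names(y) <- paste0("S", 1:4)
  x["neg", ] <- -y
  out <- pearsonScreen(x, y)
  expect_equal(out$pearson_r[out$item_id == "id"], 1)
  expect_equal(out$pearson_r[out$item_id == "neg"], -1)
  expect_equal(out$pearson_r[out$item_id == "perm"], 0.8)
  expect_false(out$defined[out$item_id == "const"])
  expect_true(is.na(out$bh_adjusted_p[out$item_id == "const"]))
})

test_that("Pearson p-values agree with permutation p-values", {
  set.seed(55)
  n <- 20
  diffs <- numeric(20)
  for (i in 1:20) {
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    pt <- cor.test(x, y)$p.value
    r0 <- abs(cor(x, y))
    perm <- replicate(4000, abs(cor(x, sample(y))))
    pp <- (1 + sum(perm >= r0)) / 4001
    diffs[i] <- abs(pt - pp)
  }
  expect_lt(max(diffs), 0.05)
  expect_lt(mean(diffs), 0.02)
})

test_that("species selection applies all three strict criteria", {
  rec <- data.frame(item_id = c("a", "b", "c", "d"),
                    pearson_r = c(0.6, 0.95, 0.95, 0.95),
                    p_value = c(1e-4, 1e-4, 0.15, 1e-4),
                    bh_adjusted_p = c(1e-3, 1e-3, 0.2, 1e-3),
                    n = 10, defined = TRUE, stringsAsFactors = FALSE)
  ab <- matrix(c(0.15, 0.15, 0.15, 0.05), nrow = 4,
               dimnames = list(c("a", "b", "c", "d"), "S1"))
  ab <- cbind(ab, S2 = ab[, 1])
  got <- selectCorrelatedSpecies(rec, ab)
  expect_equal(got, "b")  # a: r == 0.6 excluded; c: adj p; d: abundance
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  set.seed(56)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), oracleBH(p))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("Fisher overlap test reproduces hypergeometric enumeration", {
  expect_equal(fisherOverlap(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisherOverlap(0, 5, 5, 0), 2 / 252, tolerance = 1e-12)
  expect_equal(fisherOverlap(2, 2, 2, 2), 1)
  expect_error(fisherOverlap(-1, 2, 2, 2), "nonnegative")
})

test_that("size factors match the reference median-of-ratios implementation", {
  set.seed(57)
  m <- matrix(rnbinom(200 * 8, mu = 80, size = 3) + 1L, nrow = 200,
              dimnames = list(paste0("f", 1:200), paste0("S", 1:8)))
  mine <- estimateSizeFactors(m)
  ref <- suppressMessages(DESeq2::estimateSizeFactorsForMatrix(m))
  # same up to the geometric-mean-1 rescaling: ratios must agree exactly
  expect_equal(mine / mine[1], ref / ref[1], tolerance = 1e-12)
})
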