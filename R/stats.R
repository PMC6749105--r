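#' Median-of-ratios size factors
#'
#' Per-sample factors computed as the median ratio to the geometric-mean
#' pseudo-reference over features with all-positive counts, rescaled to
#' geometric mean 1. When no feature is positive in every sample the
#' function falls back to library-size ratios (with a warning).
#'
#' @param counts features-by-samples count matrix (or SummarizedExperiment
#'   with a `counts` assay).
#' @return Named positive numeric vector, one factor per sample.
#' @export
estimateSizeFactors <- function(counts) {
  m <- countsOf(counts)
  if (ncol(m) == 1) return(setNames(1, colnames(m)))
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    warning("no feature with positive counts in every sample; ",
            "falling back to library-size ratios")
    ls <- colSums(m)
    if (all(ls == 0)) stop("all samples have zero total counts")
    # zero-count samples are given the average depth so factors stay positive
    ls[ls == 0] <- exp(mean(log(ls[ls > 0])))
    sf <- ls / exp(mean(log(ls)))
    return(setNames(sf, colnames(m)))
  }
  lg <- log(m[allpos, , drop = FALSE])
  ref <- rowMeans(lg) # log geometric mean per feature
  sf <- apply(lg, 2, function(col) exp(median(col - ref)))
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

# ---- negative-binomial likelihood-ratio test -------------------------------

# NB log-likelihood at fitted means for dispersion alpha (size = 1/alpha)
.nbLogLik <- function(y, mu, alpha) {
  sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# one NB GLM fit at fixed dispersion; returns mu (or NULL on failure)
.nbFit <- function(y, X, offset, alpha) {
  fam <- MASS::negative.binomial(theta = 1 / alpha, link = "log")
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = fam, offset = offset,
                             control = list(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  fit
}

# Cox-Reid adjusted profile log-likelihood of alpha under the full model
.coxReidAPL <- function(logAlpha, y, X, offset) {
  alpha <- exp(logAlpha)
  fit <- .nbFit(y, X, offset, alpha)
  if (is.null(fit)) return(-1e10)
  mu <- fit$fitted.values
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X, X * w)
  cr <- tryCatch(0.5 * determinant(xtwx, logarithm = TRUE)$modulus,
                 error = function(e) NA_real_)
  if (is.na(cr)) return(-1e10)
  .nbLogLik(y, mu, alpha) - as.numeric(cr)
}

#' Negative-binomial likelihood-ratio differential expression
#'
#' Per feature, maximizes negative-binomial log-likelihoods of a full model
#' (intercept + group + covariates, log link, size-factor offsets) and a
#' reduced model without the group term; the LRT statistic
#' `2 * (ll_full - ll_reduced)` is compared to a chi-square with 1 df.
#' Dispersion is estimated per feature by maximizing the Cox-Reid adjusted
#' profile likelihood under the full model (method-of-moments start, floored
#' at 1e-8) and shared between the two fits; no empirical-Bayes shrinkage is
#' applied. Age is standardized before fitting (which does not change the
#' LRT). Non-converged features are flagged and reported with p = 1
#' (conservative), so they remain in the BH family.
#'
#' @param counts features-by-samples integer matrix (or SummarizedExperiment).
#' @param meta data.frame with `sample_id`, `group`, and the covariate
#'   columns; rows must cover `colnames(counts)`.
#' @param contrast length-2 character vector `(groupA, groupB)`; the log2
#'   fold change is B versus A. Samples of other groups are dropped.
#' @param covariates covariate column names included in both models;
#'   default `c("age", "gender")`.
#' @param size_factors optional named per-sample factors; estimated from the
#'   contrast samples when NULL.
#' @return data.frame with `feature_id`, `log2_fold_change`,
#'   `lrt_statistic`, `p_value`, `bh_adjusted_p`, `dispersion`, per-group
#'   median raw counts (`median_<groupA>`, `median_<groupB>`), and
#'   `converged`.
#' @export
nbLrtDe <- function(counts, meta, contrast, covariates = c("age", "gender"),
                    size_factors = NULL) {
  m <- countsOf(counts)
  meta <- as.data.frame(meta)
  rownames(meta) <- meta$sample_id
  if (!all(colnames(m) %in% meta$sample_id))
    stop("metadata does not cover all samples")
  meta <- meta[colnames(m), , drop = FALSE]
  sel <- meta$group %in% contrast
  meta <- meta[sel, , drop = FALSE]
  m <- m[, sel, drop = FALSE]
  if (length(unique(meta$group)) != 2 || min(table(meta$group)) < 3)
    stop("both contrast groups need >= 3 samples")

  meta$group <- factor(meta$group, levels = contrast)
  if ("age" %in% covariates) {
    s <- sd(meta$age)
    meta$age <- if (is.na(s) || s == 0) 0 else (meta$age - mean(meta$age)) / s
  }
  form <- stats::reformulate(c("group", covariates))
  Xf <- model.matrix(form, meta)
  Xr <- model.matrix(stats::reformulate(covariates), meta)

  if (is.null(size_factors)) size_factors <- estimateSizeFactors(m)
  off <- log(size_factors[colnames(m)])

  gi <- 2L # group coefficient column in Xf (intercept first)
  ga <- meta$group == contrast[1]
  gb <- meta$group == contrast[2]

  res <- lapply(rownames(m), function(f) {
    y <- m[f, ]
    medA <- median(y[ga]); medB <- median(y[gb])
    base <- data.frame(feature_id = f, log2_fold_change = NA_real_,
                       lrt_statistic = NA_real_, p_value = 1,
                       dispersion = NA_real_, medianA = medA, medianB = medB,
                       converged = FALSE, stringsAsFactors = FALSE)
    if (all(y == 0)) { base$lrt_statistic <- 0; base$log2_fold_change <- 0
                       base$converged <- TRUE; return(base) }
    # method-of-moments start (bounds the APL search bracket)
    yn <- y / exp(off)
    mu0 <- mean(yn)
    a0 <- max((var(yn) - mu0) / mu0^2, 1e-4, na.rm = TRUE)
    lo <- log(1e-8); hi <- log(max(100, a0 * 10))
    opt <- tryCatch(
      stats::optimize(function(la) .coxReidAPL(la, y, Xf, off),
                      interval = c(lo, hi), maximum = TRUE, tol = 1e-3),
      error = function(e) NULL)
    if (is.null(opt)) return(base)
    alpha <- max(exp(opt$maximum), 1e-8)
    ff <- .nbFit(y, Xf, off, alpha)
    fr <- .nbFit(y, Xr, off, alpha)
    if (is.null(ff) || is.null(fr)) return(base)
    stat <- max(0, 2 * (.nbLogLik(y, ff$fitted.values, alpha) -
                        .nbLogLik(y, fr$fitted.values, alpha)))
    base$log2_fold_change <- ff$coefficients[gi] / log(2)
    base$lrt_statistic <- stat
    base$p_value <- pchisq(stat, df = 1, lower.tail = FALSE)
    base$dispersion <- alpha
    base$converged <- TRUE
    base
  })
  out <- do.call(rbind, res)
  out$bh_adjusted_p <- bhAdjust(out$p_value)
  names(out)[names(out) == "medianA"] <- paste0("median_", contrast[1])
  names(out)[names(out) == "medianB"] <- paste0("median_", contrast[2])
  out <- out[, c("feature_id", "log2_fold_change", "lrt_statistic", "p_value",
                 "bh_adjusted_p", "dispersion",
                 paste0("median_", contrast), "converged")]
  rownames(out) <- NULL
  out
}

#' Filter differential-expression results
#'
#' Keeps features with BH-adjusted p strictly below `alpha` that are
#' supported by a median raw count strictly above `min_group_median` in at
#' least one of the sample groups.
#'
#' @param results data.frame from [nbLrtDe()].
#' @param counts the raw count matrix the results were computed from.
#' @param meta sample metadata (`sample_id`, `group`).
#' @param alpha adjusted-p threshold (strict `<`); default 0.05.
#' @param min_group_median median-count threshold (strict `>`); default 20.
#' @return The filtered rows of `results`.
#' @export
filterDe <- function(results, counts, meta, alpha = 0.05,
                     min_group_median = 20) {
  m <- countsOf(counts)
  meta <- as.data.frame(meta)
  groups <- split(meta$sample_id, meta$group)
  med <- vapply(results$feature_id, function(f) {
    max(vapply(groups, function(s)
      median(m[f, intersect(s, colnames(m))]), numeric(1)))
  }, numeric(1))
  out <- results[results$bh_adjusted_p < alpha & med > min_group_median, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum differential abundance
#'
#' Per taxon passing the abundance filter (mean abundance strictly above
#' `min_mean_abundance` percent in at least one group), a two-sided rank-sum
#' test between the two groups: exact null by enumeration when both groups
#' have at most 10 samples and the taxon has no ties, normal approximation
#' with tie correction otherwise. BH adjustment is applied over the tested
#' taxa. All-constant taxa give p = 1.
#'
#' @param abundance taxa-by-samples matrix of percent abundances.
#' @param meta sample metadata with `sample_id` and `group`.
#' @param contrast length-2 character vector of group names.
#' @param min_mean_abundance filter threshold in percent; default 0.1.
#' @return data.frame with `taxon`, `statistic`, `p_value`,
#'   `bh_adjusted_p`, `mean_<groupA>`, `mean_<groupB>`.
#' @export
wilcoxonDa <- function(abundance, meta, contrast, min_mean_abundance = 0.1) {
  meta <- as.data.frame(meta)
  sa <- meta$sample_id[meta$group == contrast[1]]
  sb <- meta$sample_id[meta$group == contrast[2]]
  sa <- intersect(sa, colnames(abundance))
  sb <- intersect(sb, colnames(abundance))
  if (length(sa) < 3 || length(sb) < 3)
    stop("both contrast groups need >= 3 samples")
  ma <- rowMeans(abundance[, sa, drop = FALSE])
  mb <- rowMeans(abundance[, sb, drop = FALSE])
  tested <- rownames(abundance)[pmax(ma, mb) > min_mean_abundance]
  res <- lapply(tested, function(tx) {
    x <- abundance[tx, sa]; y <- abundance[tx, sb]
    if (length(unique(c(x, y))) == 1) {
      stat <- length(x) * length(y) / 2; p <- 1
    } else {
      ties <- any(duplicated(c(x, y)))
      exact <- length(x) <= 10 && length(y) <= 10 && !ties
      wt <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                         correct = !exact))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(taxon = tx, statistic = stat, p_value = p,
               meanA = ma[[tx]], meanB = mb[[tx]], stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(taxon = character(), statistic = numeric(), p_value = numeric(),
               meanA = numeric(), meanB = numeric(), stringsAsFactors = FALSE)
  out$bh_adjusted_p <- bhAdjust(out$p_value)
  names(out)[names(out) == "meanA"] <- paste0("mean_", contrast[1])
  names(out)[names(out) == "meanB"] <- paste0("mean_", contrast[2])
  out <- out[, c("taxon", "statistic", "p_value", "bh_adjusted_p",
                 paste0("mean_", contrast))]
  rownames(out) <- NULL
  out
}

#' Pearson correlation screen
#'
#' Correlates each row of `x` with the matching row of `y` (or with the
#' single vector `y`), using the product-moment coefficient and the
#' two-sided t-transform p-value, then BH-adjusts across the screened set.
#' Rows with zero variance in either vector are flagged (r undefined) and
#' excluded from the BH family.
#'
#' @param x items-by-samples numeric matrix.
#' @param y numeric vector (same samples), or a matrix with the same
#'   rownames/colnames as `x` for paired per-item screens (e.g. DNA vs RNA
#'   abundance per taxon).
#' @return data.frame with `item_id`, `pearson_r`, `p_value`,
#'   `bh_adjusted_p`, `n`, `defined`.
#' @export
pearsonScreen <- function(x, y) {
  x <- as.matrix(x)
  paired <- is.matrix(y) || is.data.frame(y)
  if (paired) {
    y <- as.matrix(y)
    common <- intersect(colnames(x), colnames(y))
    items <- intersect(rownames(x), rownames(y))
    x <- x[items, common, drop = FALSE]
    y <- y[items, common, drop = FALSE]
  } else {
    items <- rownames(x)
    if (!is.null(names(y)) && !is.null(colnames(x)))
      y <- y[colnames(x)]
  }
  n <- ncol(x)
  if (n < 3) stop("need at least 3 paired samples")
  res <- lapply(seq_along(items), function(i) {
    xi <- x[items[i], ]
    yi <- if (paired) y[items[i], ] else y
    if (sd(xi) == 0 || sd(yi) == 0) {
      data.frame(item_id = items[i], pearson_r = NA_real_, p_value = NA_real_,
                 n = n, defined = FALSE, stringsAsFactors = FALSE)
    } else {
      ct <- cor.test(xi, yi, method = "pearson")
      data.frame(item_id = items[i], pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, n = n, defined = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$bh_adjusted_p <- NA_real_
  out$bh_adjusted_p[out$defined] <- bhAdjust(out$p_value[out$defined])
  out <- out[, c("item_id", "pearson_r", "p_value", "bh_adjusted_p", "n",
                 "defined")]
  rownames(out) <- NULL
  out
}

#' Select species with high DNA-RNA concordance
#'
#' Strict thresholds on all three criteria: mean abundance above
#' `min_abundance` percent in at least one sample group, Pearson r above
#' `min_r`, and BH-adjusted p below `alpha`.
#'
#' @param records data.frame from [pearsonScreen()] at species rank.
#' @param abundance species-by-samples percent abundance matrix used for the
#'   abundance filter.
#' @param meta optional metadata (`sample_id`, `group`); with NULL the
#'   overall mean is used.
#' @param min_abundance percent threshold (strict `>`); default 0.1.
#' @param min_r correlation threshold (strict `>`); default 0.6.
#' @param alpha adjusted-p threshold (strict `<`); default 0.05.
#' @return Character vector of selected species ids.
#' @export
selectCorrelatedSpecies <- function(records, abundance, meta = NULL,
                                    min_abundance = 0.1, min_r = 0.6,
                                    alpha = 0.05) {
  if (is.null(meta)) {
    maxMean <- rowMeans(abundance)
  } else {
    meta <- as.data.frame(meta)
    groups <- split(meta$sample_id, meta$group)
    gm <- vapply(groups, function(s)
      rowMeans(abundance[, intersect(s, colnames(abundance)), drop = FALSE]),
      numeric(nrow(abundance)))
    maxMean <- apply(as.matrix(gm), 1, max)
    names(maxMean) <- rownames(abundance)
  }
  ok <- records$defined &
    records$pearson_r > min_r &
    records$bh_adjusted_p < alpha &
    records$item_id %in% names(maxMean)[maxMean > min_abundance]
  sort(records$item_id[ok])
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`), returned in
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Fisher's exact test on a 2x2 overlap table
#'
#' Exact hypergeometric two-sided p-value (sum of table probabilities not
#' exceeding the observed table's probability), e.g. for the overlap between
#' a classifier feature signature and an external differential-expression
#' list over an explicit background universe.
#'
#' @param a_and_b,a_only,b_only,neither nonnegative integer cells.
#' @return Two-sided p-value.
#' @export
fisherOverlap <- function(a_and_b, a_only, b_only, neither) {
  cells <- c(a_and_b, a_only, b_only, neither)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be nonnegative integers")
  fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}
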