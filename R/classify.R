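# Random Forest evaluation protocol: stratified repeated cross-validation,
# rank-based AUC, leakage-safe feature ranking.

.PROFILE_TYPES <- c("bDNA", "bsRNA", "hsa_miRNA", "hsa_sncRNA")

#' All category subsets of the four profile types
#'
#' @param preset `"all"` for the 15 nonempty subsets of
#'   {bDNA, bsRNA, hsa_miRNA, hsa_sncRNA}; `"paper14"` for the
#'   14-category preset that drops the {hsa_miRNA, hsa_sncRNA} pair.
#' @return List of character vectors.
#' @export
categoryPresets <- function(preset = c("all", "paper14")) {
  preset <- match.arg(preset)
  subsets <- unlist(lapply(seq_along(.PROFILE_TYPES), function(k)
    utils::combn(.PROFILE_TYPES, k, simplify = FALSE)), recursive = FALSE)
  if (preset == "paper14")
    subsets <- Filter(function(s)
      !setequal(s, c("hsa_miRNA", "hsa_sncRNA")), subsets)
  subsets
}

#' Assemble a feature table from quantitative profiles
#'
#' Count-type profiles (`hsa_miRNA`, `hsa_sncRNA`) are transformed to
#' `log10(1 + CPM)` where CPM are counts-per-million after median-of-ratios
#' size-factor normalization; abundance-type profiles (`bDNA`, `bsRNA`) are
#' used as percent values. Columns are concatenated with provenance
#' prefixes, so feature names stay unique across types.
#'
#' @param profiles named list mapping profile type to a features-by-samples
#'   matrix (or SummarizedExperiment).
#' @param category character vector: which types to include.
#' @param count_types types to be treated as counts; default
#'   `c("hsa_miRNA", "hsa_sncRNA")`.
#' @return Samples-by-features numeric matrix with `type|feature` column
#'   names.
#' @export
assembleFeatures <- function(profiles, category,
                             count_types = c("hsa_miRNA", "hsa_sncRNA")) {
  category <- match.arg(category, .PROFILE_TYPES, several.ok = TRUE)
  missing <- setdiff(category, names(profiles))
  if (length(missing))
    stop("profiles missing for type(s): ", paste(missing, collapse = ", "))
  samples <- Reduce(intersect, lapply(profiles[category],
                                      function(p) colnames(countsOf(p))))
  blocks <- lapply(category, function(ty) {
    m <- countsOf(profiles[[ty]])
    bad <- setdiff(colnames(countsOf(profiles[[ty]])), samples)
    if (ty %in% count_types) {
      sf <- estimateSizeFactors(m)
      norm <- sweep(m, 2, sf, "/")
      tot <- colSums(norm)
      tot[tot == 0] <- 1
      m <- log10(1 + sweep(norm, 2, tot, "/") * 1e6)
    }
    m <- t(m[, samples, drop = FALSE])
    colnames(m) <- paste0(ty, "|", colnames(m))
    m
  })
  out <- do.call(cbind, blocks)
  all_samples <- unique(unlist(lapply(profiles[category],
                                      function(p) colnames(countsOf(p)))))
  dropped <- setdiff(all_samples, samples)
  if (length(dropped))
    stop("sample(s) missing from a requested profile: ",
         paste(dropped, collapse = ", "))
  out
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (TRUE = positive) or factor/character with
#'   `positive` naming the positive class.
#' @param positive positive class label when `labels` is not logical.
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(scores, labels, positive = NULL) {
  if (!is.logical(labels)) {
    if (is.null(positive)) stop("positive class must be given")
    labels <- labels == positive
  }
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment; error when a fold would miss a class
.stratifiedFolds <- function(labels, folds) {
  if (min(table(labels)) < folds)
    stop("stratification error: a fold would contain only one class ",
         "(smallest class has fewer samples than folds)")
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

.fitForest <- function(x, y, numTrees, seed, importance = "impurity") {
  df <- as.data.frame(x)
  colnames(df) <- make.names(colnames(x))
  ranger::ranger(x = df, y = y, num.trees = numTrees, probability = TRUE,
                 importance = importance, seed = seed, num.threads = 1,
                 min.node.size = 1)
}

.predictPositive <- function(fit, x, positive) {
  df <- as.data.frame(x)
  colnames(df) <- make.names(colnames(x))
  pr <- predict(fit, data = df, num.threads = 1)$predictions
  pr[, positive]
}

#' Repeated stratified cross-validation of a Random Forest
#'
#' Each experiment is a `folds`-fold stratified cross-validation iterated
#' `iterations` times (per-iteration seeds derived as `seed + iteration`),
#' producing `folds * iterations` test AUCs from positive-class
#' probabilities. Feature importances (mean impurity decrease) are computed
#' on training data only and averaged across splits, so test folds never
#' influence the ranking.
#'
#' @param x samples-by-features matrix (see [assembleFeatures()]).
#' @param labels factor/character class labels, one per row of `x`.
#' @param positive positive class label.
#' @param folds folds per iteration; default 10.
#' @param iterations repetitions; default 20.
#' @param seed base seed.
#' @param num_trees trees per forest; default 500.
#' @return List (class `fecoduo_cv`) with `auc_per_test`, `mean_auc`,
#'   `sd_auc`, `feature_importances`, `folds`, `iterations`.
#' @export
crossValidate <- function(x, labels, positive, folds = 10L, iterations = 20L,
                          seed = 1L, num_trees = 500L) {
  labels <- as.character(labels)
  if (!positive %in% labels) stop("positive class absent from labels")
  y <- factor(labels, levels = c(setdiff(unique(labels), positive), positive))
  aucs <- numeric(0)
  imp <- setNames(numeric(ncol(x)), colnames(x))
  nimp <- 0L
  for (it in seq_len(iterations)) {
    set.seed(seed + it)
    fold <- .stratifiedFolds(labels, folds)
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      fit <- .fitForest(x[tr, , drop = FALSE], droplevels(y[tr]),
                        num_trees, seed = seed + it * 1000L + f)
      p <- .predictPositive(fit, x[te, , drop = FALSE], positive)
      aucs <- c(aucs, aucScore(p, labels[te] == positive))
      imp <- imp + fit$variable.importance[make.names(colnames(x))]
      nimp <- nimp + 1L
    }
  }
  mimp <- imp / nimp
  names(mimp) <- colnames(x)
  structure(list(auc_per_test = aucs, mean_auc = mean(aucs),
                 sd_auc = sd(aucs),
                 feature_importances = mimp[order(-mimp)],
                 folds = folds, iterations = iterations),
            class = "fecoduo_cv")
}

#' Cross-validated AUC as a function of the number of top-ranked features
#'
#' Within every cross-validation split, features are ranked by the impurity
#' importance of a forest trained on the training fold only; for each grid
#' value n the classifier is retrained on the training fold restricted to
#' that split's top-n features and evaluated on the held-out fold. Rankings
#' therefore never see test data.
#'
#' @inheritParams crossValidate
#' @param grid integer vector of feature-set sizes (values capped at the
#'   total feature count).
#' @param assert_no_leakage re-derive every split's ranking after zeroing the
#'   test-fold rows of the feature matrix and stop if any ranking changes
#'   (a construction-level leakage check); default FALSE.
#' @return List with `sweep_curve` (data.frame `n_features`, `mean_auc`,
#'   `sd_auc`), `best_n`, per-test AUCs, and the per-split top-feature
#'   selection frequencies.
#' @export
featureSweep <- function(x, labels, positive, grid, folds = 10L,
                         iterations = 20L, seed = 1L, num_trees = 500L,
                         assert_no_leakage = FALSE) {
  labels <- as.character(labels)
  grid <- sort(unique(pmin(as.integer(grid), ncol(x))))
  y <- factor(labels, levels = c(setdiff(unique(labels), positive), positive))
  aucs <- matrix(NA_real_, nrow = folds * iterations, ncol = length(grid),
                 dimnames = list(NULL, grid))
  chosen <- list()
  row <- 0L
  for (it in seq_len(iterations)) {
    set.seed(seed + it)
    fold <- .stratifiedFolds(labels, folds)
    for (f in seq_len(folds)) {
      row <- row + 1L
      tr <- fold != f; te <- !tr
      ranker <- .fitForest(x[tr, , drop = FALSE], droplevels(y[tr]),
                           num_trees, seed = seed + it * 1000L + f)
      rk <- ranker$variable.importance[make.names(colnames(x))]
      ord <- order(rk, decreasing = TRUE)
      if (assert_no_leakage) {
        xz <- x
        xz[te, ] <- 0
        rk2 <- .fitForest(xz[tr, , drop = FALSE], droplevels(y[tr]),
                          num_trees, seed = seed + it * 1000L + f
                          )$variable.importance[make.names(colnames(x))]
        stopifnot(identical(rk, rk2))
      }
      for (gi in seq_along(grid)) {
        keep <- ord[seq_len(grid[gi])]
        fit <- .fitForest(x[tr, keep, drop = FALSE], droplevels(y[tr]),
                          num_trees, seed = seed + it * 1000L + f + 7L * gi)
        p <- .predictPositive(fit, x[te, keep, drop = FALSE], positive)
        aucs[row, gi] <- aucScore(p, labels[te] == positive)
        if (gi == 1L)
          chosen[[row]] <- colnames(x)[keep]
      }
    }
  }
  curve <- data.frame(n_features = grid,
                      mean_auc = colMeans(aucs),
                      sd_auc = apply(aucs, 2, sd))
  rownames(curve) <- NULL
  best <- grid[which.max(curve$mean_auc)]
  list(sweep_curve = curve, best_n = best,
       auc_per_test = aucs,
       top_feature_frequency = sort(table(unlist(chosen)), decreasing = TRUE))
}

#' Run the full classification experiment grid
#'
#' Cartesian product of data categories and group comparisons. The positive
#' class is carcinoma when present in the comparison, adenoma otherwise.
#'
#' @param profiles named list of the four profile matrices (see
#'   [assembleFeatures()]).
#' @param meta sample metadata with `sample_id` and `group`.
#' @param categories list of type subsets, or a preset name for
#'   [categoryPresets()]; default `"paper14"`.
#' @param comparisons list of length-2 group pairs; default the three
#'   pairwise contrasts.
#' @inheritParams crossValidate
#' @return List with `summary` (data.frame: comparison, category, positive
#'   class, mean/sd AUC) and `results` (the per-experiment `fecoduo_cv`
#'   objects).
#' @export
runExperimentGrid <- function(profiles, meta, categories = "paper14",
                              comparisons = list(c("healthy", "carcinoma"),
                                                 c("adenoma", "carcinoma"),
                                                 c("healthy", "adenoma")),
                              folds = 10L, iterations = 20L, seed = 1L,
                              num_trees = 500L) {
  if (is.character(categories) && length(categories) == 1)
    categories <- categoryPresets(categories)
  meta <- as.data.frame(meta)
  results <- list()
  rows <- list()
  for (cmp in comparisons) {
    sel <- meta$group %in% cmp
    sub <- meta[sel, , drop = FALSE]
    positive <- if ("carcinoma" %in% cmp) "carcinoma" else "adenoma"
    for (cat in categories) {
      x <- assembleFeatures(profiles, cat)
      x <- x[sub$sample_id, , drop = FALSE]
      cv <- crossValidate(x, sub$group, positive, folds = folds,
                          iterations = iterations, seed = seed,
                          num_trees = num_trees)
      key <- sprintf("%s_vs_%s|%s", cmp[1], cmp[2], paste(cat, collapse = "+"))
      results[[key]] <- cv
      rows[[key]] <- data.frame(
        comparison = paste(cmp[1], "vs", cmp[2]),
        category = paste(cat, collapse = "+"),
        positive = positive,
        mean_auc = cv$mean_auc, sd_auc = cv$sd_auc,
        n_tests = length(cv$auc_per_test),
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, results = results)
}
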