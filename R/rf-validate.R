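# Random-forest cross-validation of the latent class solution: predict
# modal class labels from the seven indicators, report stratified 10-fold
# cross-validated accuracy, out-of-bag error, and permutation-based
# variable importance (mean decrease accuracy). The forest itself is the
# randomForest package's bagged-tree ensemble; this stage validates the
# class solution, it is not the mixture engine.

#' Random-forest configuration
#'
#' @param n_tree trees to grow (default 1000).
#' @param features_per_split candidate features per split (default
#'   `floor(sqrt(p))` computed at fit time when `NULL`).
#' @param folds cross-validation folds (default 10).
#' @param seed RNG seed.
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_tree = 1000L, features_per_split = NULL,
                      folds = 10L, seed = 1L) {
  stopifnot(n_tree >= 1L, folds >= 2L)
  if (!is.null(features_per_split)) stopifnot(features_per_split >= 1L)
  structure(list(n_tree = as.integer(n_tree),
                 features_per_split = features_per_split,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "rf_config")
}

# Stratified fold assignment: within each class, subjects are dealt round-
# robin into folds in a random order.
.stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Cross-validate class labels with a random forest
#'
#' Stratified k-fold cross-validation of a random-forest classifier
#' (bootstrap-resampled trees, random feature subset per split, majority
#' vote) predicting the modal latent-class labels from the indicator
#' matrix. Also reports the out-of-bag error of a forest grown on the full
#' data and its permutation importance ranking.
#'
#' @param X a `risk_matrix` or numeric matrix of indicators.
#' @param labels class labels (factor or integer).
#' @param config an [rf_config()].
#' @return list of class `rf_validation`: `cv_accuracy`, per-fold
#'   accuracies, `oob_error`, `importance` (mean decrease accuracy,
#'   descending), `ranking`, and the full-data `forest`.
#' @export
rf_cross_validate <- function(X, labels, config = rf_config()) {
  x <- .as_risk_matrix(X)$x
  if (anyNA(x)) stop("indicator matrix must be complete for the forest")
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 classes")
  mtry <- config$features_per_split
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(config$seed)

  fold <- .stratified_folds(labels, config$folds)
  if (any(vapply(seq_len(config$folds), function(f) {
    length(unique(labels[fold != f])) < nlevels(labels)
  }, TRUE))) {
    stop("stratification failure: a class is absent from a training fold")
  }
  correct <- logical(length(labels))
  fold_acc <- numeric(config$folds)
  for (f in seq_len(config$folds)) {
    tr <- fold != f
    rf <- randomForest::randomForest(x[tr, , drop = FALSE], labels[tr],
                                     ntree = config$n_tree, mtry = mtry)
    pred <- stats::predict(rf, x[!tr, , drop = FALSE])
    correct[!tr] <- pred == labels[!tr]
    fold_acc[f] <- mean(pred == labels[!tr])
  }

  full <- randomForest::randomForest(x, labels, ntree = config$n_tree,
                                     mtry = mtry, importance = TRUE)
  oob_error <- mean(full$predicted != labels)
  imp <- randomForest::importance(full, type = 1, scale = FALSE)[, 1]
  imp <- sort(imp, decreasing = TRUE)

  structure(list(
    cv_accuracy = mean(correct), fold_accuracy = fold_acc,
    oob_error = oob_error, importance = imp, ranking = names(imp),
    config = config, forest = full,
    majority_share = max(table(labels)) / length(labels)
  ), class = "rf_validation")
}

#' Permutation importance of each indicator
#'
#' Mean decrease in out-of-bag accuracy when each variable's values are
#' permuted across the trees of a fitted forest, ranked descending. When
#' given an `rf_validation` report, re-uses its full-data forest.
#'
#' @param forest a `randomForest` fit with `importance = TRUE`, or an
#'   `rf_validation` report.
#' @param ... unused.
#' @return data frame with `variable`, `mean_decrease_accuracy`, `rank`.
#' @export
permutation_importance <- function(forest, ...) {
  if (inherits(forest, "rf_validation")) forest <- forest$forest
  imp <- randomForest::importance(forest, type = 1, scale = FALSE)[, 1]
  ord <- order(imp, decreasing = TRUE)
  data.frame(variable = names(imp)[ord],
             mean_decrease_accuracy = unname(imp[ord]),
             rank = seq_along(imp))
}

#' @export
print.rf_validation <- function(x, ...) {
  cat(sprintf(
    "Random-forest validation: %d trees, %d-fold stratified CV\n",
    x$config$n_tree, x$config$folds))
  cat(sprintf("  CV accuracy = %.3f   OOB error = %.3f   majority baseline = %.3f\n",
              x$cv_accuracy, x$oob_error, x$majority_share))
  cat("  importance ranking:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}
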