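#' Cross-validated random-forest discrimination
#'
#' Trains a random forest to discriminate two classes (e.g. cases vs
#' controls from fungal genus abundances plus clinical covariates), with
#' stratified k-fold cross-validation. Out-of-fold class probabilities are
#' pooled across folds to one AUC (per-fold AUCs are also reported); a
#' final forest fitted on all samples supplies the out-of-bag error and
#' both importance measures: MeanDecreaseGini (impurity-based, always
#' non-negative) and permutation importance (MeanDecreaseAccuracy, which
#' can legitimately be negative for uninformative features). Trees are
#' invariant to monotone transforms of features, so covariates such as IgE
#' need no log or rank transformation.
#'
#' @param features Data frame or matrix of predictors (samples in rows).
#' @param labels Two-level factor (or coercible) of class labels.
#' @param n_folds Cross-validation folds (default 10; reduced with a
#'   warning when the smallest class cannot populate that many folds).
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed controlling folds and forests.
#' @return Object of class `rf_report`: `importance` tibble (`feature`,
#'   `mean_decrease_gini`, `permutation_importance`), `cv_auc`,
#'   `per_fold_auc`, `oob_error`, `n_folds`, `n_trees`, `seed`.
#' @export
cv_random_forest <- function(features, labels, n_folds = 10, n_trees = 500,
                             seed = 1L) {
  features <- as.data.frame(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) abort("Labels must contain at least two classes.")
  if (nlevels(labels) != 2) abort("AUC-based evaluation expects exactly two classes.")
  min_class <- min(table(labels))
  if (n_folds > min_class) {
    warn(sprintf("Reducing folds from %d to %d (smallest class size).",
                 n_folds, min_class))
    n_folds <- min_class
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  pos <- levels(labels)[2]
  scores <- rep(NA_real_, length(labels))
  per_fold <- rep(NA_real_, n_folds)
  for (f in seq_len(n_folds)) {
    train <- fold != f
    fit <- randomForest::randomForest(features[train, , drop = FALSE],
                                      labels[train], ntree = n_trees)
    pr <- predict(fit, features[!train, , drop = FALSE], type = "prob")[, pos]
    scores[!train] <- pr
    if (length(unique(labels[!train])) == 2) {
      per_fold[f] <- as.numeric(pROC::auc(labels[!train], pr,
                                          levels = levels(labels),
                                          direction = "<", quiet = TRUE))
    }
  }
  cv_auc <- as.numeric(pROC::auc(labels, scores, levels = levels(labels),
                                 direction = "<", quiet = TRUE))
  final <- randomForest::randomForest(features, labels, ntree = n_trees,
                                      importance = TRUE)
  imp <- randomForest::importance(final)
  structure(list(
    importance = tibble::tibble(
      feature = rownames(imp),
      mean_decrease_gini = unname(imp[, "MeanDecreaseGini"]),
      permutation_importance = unname(imp[, "MeanDecreaseAccuracy"])
    ) |> dplyr::arrange(dplyr::desc(.data$mean_decrease_gini)),
    cv_auc = cv_auc,
    per_fold_auc = per_fold,
    oob_error = unname(final$err.rate[n_trees, "OOB"]),
    n_folds = n_folds, n_trees = n_trees, seed = seed
  ), class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf("# Random forest: %d-fold CV AUC = %.3f, OOB error = %.3f (%d trees)\n",
              x$n_folds, x$cv_auc, x$oob_error, x$n_trees))
  print(x$importance, ...)
  invisible(x)
}
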