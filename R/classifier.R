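#' Train the gradient-boosted classifier
#'
#' Fits a gradient-boosted decision-tree ensemble (xgboost, leaf-wise growth
#' via `grow_policy = "lossguide"` with a `max_leaves` cap, histogram tree
#' method) on a labelled set and optionally reports stratified k-fold
#' cross-validated accuracy, precision and ROC-AUC.  The deployed model is
#' always refit on the full input; cross-validation is reporting only.
#'
#' Hyperparameters use the package-wide naming of
#' [default_classifier_params()] (`n_estimators`, `learning_rate`,
#' `num_leaves`, `colsample_bytree`, `reg_alpha`, `reg_lambda`,
#' `min_split_gain`, `min_child_weight`) and are mapped onto the
#' corresponding xgboost parameters.  Note that `min_child_weight` is a leaf
#' hessian floor: for logistic loss each row contributes at most 0.25, so
#' the large-data default of 40 requires roughly 320 rows per leaf and must
#' be lowered for small data sets.
#'
#' @param labelled A [labelled_set()] with both classes present (train after
#'   [smote_balance()]).
#' @param params Named list of hyperparameters; missing entries are filled
#'   from [default_classifier_params()].
#' @param seed Integer seed (xgboost `seed` parameter and fold assignment).
#' @param cv_folds Stratified folds for the performance report; 0 skips it.
#' @return Object of class `"heal_classifier"`: `list(booster,
#'   feature_names, params, cv_scores)` where `cv_scores` is a named vector
#'   (accuracy, precision, roc_auc) or `NULL`.
#' @export
train_classifier <- function(labelled, params = list(), seed = 1L, cv_folds = 5L) {
  assert_two_classes(labelled)
  params <- utils::modifyList(default_classifier_params(), params)
  x <- unclass(labelled$table)
  y <- as.numeric(labelled$labels)

  cv_scores <- NULL
  if (cv_folds > 0L) {
    folds <- stratified_folds(y, cv_folds, seed)
    preds <- rep(NA_real_, length(y))
    for (f in seq_len(cv_folds)) {
      te <- folds == f
      if (length(unique(y[!te])) < 2L) next  # degenerate fold, skip
      fit <- xgb_fit(x[!te, , drop = FALSE], y[!te], params, seed)
      preds[te] <- xgb_score(fit, x[te, , drop = FALSE])
    }
    ok <- !is.na(preds)
    m <- compute_metrics(as.integer(preds[ok] >= 0.5), preds[ok], y[ok])
    cv_scores <- c(accuracy = m$accuracy, precision = m$precision,
                   roc_auc = m$roc_auc)
  }

  booster <- xgb_fit(x, y, params, seed)
  structure(list(booster = booster, feature_names = colnames(x),
                 params = params, cv_scores = cv_scores),
            class = "heal_classifier")
}

# map package-level hyperparameter names onto xgboost and fit
xgb_fit <- function(x, y, params, seed) {
  xgb_params <- list(
    objective        = "binary:logistic",
    eta              = params$learning_rate,
    max_leaves       = params$num_leaves,
    grow_policy      = "lossguide",
    tree_method      = "hist",
    max_depth        = 0,
    colsample_bytree = params$colsample_bytree,
    alpha            = params$reg_alpha,
    lambda           = params$reg_lambda,
    gamma            = params$min_split_gain,
    min_child_weight = params$min_child_weight,
    base_score       = 0.5,
    nthread          = 1,
    seed             = seed
  )
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(xgb_params, dtrain, nrounds = params$n_estimators,
                     verbose = 0)
}

xgb_score <- function(booster, x) {
  stats::setNames(
    stats::predict(booster, xgboost::xgb.DMatrix(x, nthread = 1)),
    rownames(x)
  )
}

#' Positive-class probabilities from a trained classifier
#'
#' @param object A `"heal_classifier"` from [train_classifier()].
#' @param table A [feature_table()] (or a [pool()] / [labelled_set()], whose
#'   table is used); must contain the model's feature columns.
#' @param ... Unused.
#' @return Named numeric vector of probabilities in `[0,1]`.
#' @export
predict.heal_classifier <- function(object, table, ...) {
  if (inherits(table, "pool") || inherits(table, "labelled_set")) {
    table <- table$table
  }
  m <- unclass(as_feature_table(table))
  missing_cols <- setdiff(object$feature_names, colnames(m))
  if (length(missing_cols)) {
    stop("table lacks model features: ",
         paste(utils::head(missing_cols, 5), collapse = ", "), call. = FALSE)
  }
  xgb_score(object$booster, m[, object$feature_names, drop = FALSE])
}

#' @export
print.heal_classifier <- function(x, ...) {
  cat(sprintf("<heal_classifier> gradient-boosted trees on %d features\n",
              length(x$feature_names)))
  if (!is.null(x$cv_scores)) {
    cat("  CV:", paste(sprintf("%s=%.3f", names(x$cv_scores), x$cv_scores),
                       collapse = ", "), "\n")
  }
  invisible(x)
}

# stratified fold assignment: within each class, samples are dealt round-robin
# into folds in a seeded random order
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Confusion-matrix metrics and rank-based ROC-AUC
#'
#' @param predicted Integer 0/1 predicted labels.
#' @param scores Optional numeric scores for ROC-AUC (the probability of the
#'   positive class); `NULL` omits the AUC.
#' @param truth Integer 0/1 ground-truth labels, aligned with `predicted`.
#' @return Object of class `"heal_metrics"`: confusion counts (TP/FP/TN/FN),
#'   `accuracy`, `precision` (`NA` when no positive predictions), and
#'   `roc_auc` computed as the Mann-Whitney rank statistic over `scores`
#'   (`NA` when `scores` is `NULL` or the truth is single-class; tied scores
#'   receive half credit).
#' @export
compute_metrics <- function(predicted, scores = NULL, truth) {
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  if (!length(truth) || length(predicted) != length(truth)) {
    stop("'predicted' and 'truth' must be non-empty and aligned", call. = FALSE)
  }
  tp <- sum(predicted == 1L & truth == 1L)
  fp <- sum(predicted == 1L & truth == 0L)
  tn <- sum(predicted == 0L & truth == 0L)
  fn <- sum(predicted == 0L & truth == 1L)
  acc <- (tp + tn) / length(truth)
  prec <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  auc <- NA_real_
  if (!is.null(scores) && length(unique(truth)) == 2L) {
    r <- rank(scores)                       # midranks: ties get half credit
    n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
    auc <- (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 accuracy = acc, precision = prec, roc_auc = auc),
            class = "heal_metrics")
}

#' @export
print.heal_metrics <- function(x, ...) {
  cat(sprintf("<heal_metrics> TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  accuracy %.3f | precision %s | ROC-AUC %s\n",
              x$accuracy,
              ifelse(is.na(x$precision), "NA", sprintf("%.3f", x$precision)),
              ifelse(is.na(x$roc_auc), "NA", sprintf("%.3f", x$roc_auc))))
  invisible(x)
}
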