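#' Default gradient-boosting hyperparameters
#'
#' The classifier defaults used throughout the package: a gradient-boosted
#' decision-tree ensemble with 600 trees, learning rate 0.05, 32 leaves per
#' tree, 20% feature subsampling per tree, L1/L2 regularisation 3/1, minimum
#' split gain 0.01 and a minimum child (hessian) weight of 40.  These values
#' were tuned for large feature matrices (thousands of samples, hundreds of
#' selected features); `min_child_weight` is a leaf hessian floor, so on
#' small data sets (under a few hundred training rows) it prevents any split
#' and must be lowered — see the methods vignette and the examples, which use
#' `min_child_weight = 2` for desk-scale data.
#'
#' @return Named list of hyperparameters.
#' @export
default_classifier_params <- function() {
  list(
    n_estimators     = 600,
    learning_rate    = 0.05,
    num_leaves       = 32,
    colsample_bytree = 0.2,
    reg_alpha        = 3,
    reg_lambda       = 1,
    min_split_gain   = 0.01,
    min_child_weight = 40
  )
}

#' Run configuration for the active-learning loop
#'
#' Bundles every tunable of the annotation loop and its benchmark harness.
#'
#' @param boundary Classification boundary in (0,1): pool samples scoring at
#'   or above it are treated as provisional positives.  Default 0.6.
#' @param threshold Certainty threshold in (0,1]: the user floor for the
#'   dynamic positive cut-off `sup`; no pseudo-positive is ever admitted with
#'   a score below it.  Must be >= `boundary`.  Default 0.9.
#' @param batch_size Batch size for the benchmark strategies (uncertainty and
#'   random sampling); the certainty strategy's batch is cut-off-driven and
#'   ignores it.  Default 20.
#' @param stop_fraction Stop once this fraction of the full data set is
#'   labelled.  Default 0.90.
#' @param top_k_features Number of top-ranked features kept by per-iteration
#'   permutation-importance selection.  Default 400.
#' @param corr_cutoff Pairwise |Pearson r| above which features are
#'   considered redundant.  Default 0.70.
#' @param jaccard_tau Jaccard threshold for gene-set redundancy edges.
#'   Default 0.3.
#' @param classifier_params Named list overriding
#'   [default_classifier_params()] entries.
#' @param seed Integer master seed; per-iteration seeds are derived from it.
#' @param max_iterations Iteration cap. Default 100.
#' @param cv_folds Folds for the per-iteration cross-validated performance
#'   report (accuracy/precision/ROC-AUC); 0 disables the report.  Reporting
#'   only — the deployed model is always refit on the full balanced set.
#'   Default 5.
#' @param smote_k Number of minority nearest neighbours used by SMOTE.
#'   Default 5.
#' @param stall_fallback What to do when the certainty heuristic selects an
#'   empty batch: `"stop"` terminates with status `"stalled"`; `"top1"`
#'   force-adds the single highest-scoring sample as a positive and the
#'   single lowest-scoring as a negative and continues.
#' @return Object of class `"heal_config"` (a validated named list).
#' @export
heal_config <- function(boundary = 0.6,
                        threshold = 0.9,
                        batch_size = 20L,
                        stop_fraction = 0.90,
                        top_k_features = 400L,
                        corr_cutoff = 0.70,
                        jaccard_tau = 0.3,
                        classifier_params = list(),
                        seed = 1L,
                        max_iterations = 100L,
                        cv_folds = 5L,
                        smote_k = 5L,
                        stall_fallback = c("stop", "top1")) {
  stall_fallback <- match.arg(stall_fallback)
  stopifnot(
    is.numeric(boundary), length(boundary) == 1, boundary > 0, boundary < 1,
    is.numeric(threshold), length(threshold) == 1, threshold > 0, threshold <= 1,
    is.numeric(stop_fraction), stop_fraction > 0, stop_fraction <= 1,
    batch_size >= 1, top_k_features >= 1, max_iterations >= 1,
    cv_folds >= 0, smote_k >= 1
  )
  if (threshold < boundary) {
    stop("'threshold' must be >= 'boundary'", call. = FALSE)
  }
  params <- utils::modifyList(default_classifier_params(), classifier_params)
  unknown <- setdiff(names(classifier_params), names(default_classifier_params()))
  if (length(unknown)) {
    stop("unknown classifier parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    boundary = boundary, threshold = threshold,
    batch_size = as.integer(batch_size), stop_fraction = stop_fraction,
    top_k_features = as.integer(top_k_features), corr_cutoff = corr_cutoff,
    jaccard_tau = jaccard_tau, classifier_params = params,
    seed = as.integer(seed), max_iterations = as.integer(max_iterations),
    cv_folds = as.integer(cv_folds), smote_k = as.integer(smote_k),
    stall_fallback = stall_fallback
  ), class = "heal_config")
}

#' @export
print.heal_config <- function(x, ...) {
  cat("<heal_config>\n")
  cat(sprintf("  boundary %.2f | threshold %.2f | batch %d | stop at %.0f%% labelled\n",
              x$boundary, x$threshold, x$batch_size, 100 * x$stop_fraction))
  cat(sprintf("  top-k features %d | corr cutoff %.2f | seed %d | max iterations %d\n",
              x$top_k_features, x$corr_cutoff, x$seed, x$max_iterations))
  cp <- x$classifier_params
  cat("  classifier:", paste(sprintf("%s=%s", names(cp), unlist(cp)), collapse = ", "), "\n")
  invisible(x)
}

# deterministic per-iteration seed derived from (master seed, iteration, salt);
# kept below 2^31 so it is a valid R integer seed
derive_seed <- function(seed, alpha, salt = 0L) {
  as.integer((as.double(seed) * 48271 + alpha * 1009 + salt * 97) %% 2147483647)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
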