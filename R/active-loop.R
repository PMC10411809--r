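#' Replace batch pre-labels with ground truth (simulated expert)
#'
#' The benchmark stand-in for the human expert: every pre-label in the batch
#' is replaced by the ground-truth label of the sample.
#'
#' @param batch A `selected_batch` (from [uncertainty_select()] or
#'   [random_select()]).
#' @param truth Named 0/1 vector covering every batch sample ID.
#' @return The corrected `selected_batch`.
#' @export
simulated_oracle <- function(batch, truth) {
  ids <- batch$samples$sample_id
  missing_ids <- setdiff(ids, names(truth))
  if (length(missing_ids)) {
    stop("ground truth missing for: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  batch$samples$pseudo_label <- as.integer(truth[ids])
  batch
}

#' Run the heuristic-enabled annotation loop
#'
#' The main iteration engine.  Per iteration: the labelled set is
#' SMOTE-balanced, the top-k features are selected by out-of-bag permutation
#' importance, a gradient-boosted classifier is trained and scores the
#' pool, the certainty heuristic ([heuristic_select()]) picks a batch of
#' high-confidence samples, and the batch enters the labelled set with its
#' pseudo-labels (`provenance = "pseudo"`) while leaving the pool.  The loop
#' stops when the labelled fraction reaches `config$stop_fraction`
#' (status `"completed"`), when the heuristic selects an empty batch
#' (status `"stalled"`, unless `config$stall_fallback = "top1"`), or after
#' `config$max_iterations` iterations (status `"max_iter"`).
#'
#' SMOTE-synthetic rows are regenerated each iteration from the real
#' labelled rows only and never enter the labelled set permanently.
#'
#' @param labelled Seed [labelled_set()] with both classes.
#' @param pool Unlabelled [pool()] with the same feature columns.
#' @param config A [heal_config()].
#' @param normalize Apply [preprocess_dataset()] (z-score + correlation
#'   filter, fit once on the labelled+pool union) before looping.  Default
#'   `TRUE`.
#' @return Object of class `"heal_result"`; see Details.
#' @details The result contains `labelled` (seed + accumulated batches),
#'   `pool` (residual unlabelled samples), `history` (one row per iteration:
#'   `alpha`, `sup`, `inf`, `n_selected`, `n_pos_selected`,
#'   `n_neg_selected`, `cv_accuracy`, `cv_precision`, `cv_roc_auc`,
#'   `labelled_fraction`), `assignments` (one row per label assigned during
#'   the run: `sample_id`, `label`, `score`, `iteration`, `provenance`),
#'   `status`, `model` (the final classifier) and `config`.
#' @export
run_heal <- function(labelled, pool, config = heal_config(), normalize = TRUE) {
  run_active_loop(labelled, pool, config, strategy = "certainty",
                  truth = NULL, normalize = normalize)
}

#' Run one annotation strategy over a labelled/pool split
#'
#' Shared engine behind [run_heal()] and [run_benchmark()].  With
#' `strategy = "certainty"` batches keep their heuristic pseudo-labels; with
#' `"uncertainty"` or `"random"` each batch is corrected by the
#' [simulated_oracle()] (requiring `truth`).
#'
#' @inheritParams run_heal
#' @param strategy One of `"certainty"`, `"uncertainty"`, `"random"`.
#' @param truth Named ground-truth labels over pool IDs (oracle strategies
#'   only).
#' @return A `"heal_result"` (see [run_heal()]).
#' @export
run_active_loop <- function(labelled, pool, config = heal_config(),
                            strategy = c("certainty", "uncertainty", "random"),
                            truth = NULL, normalize = TRUE) {
  strategy <- match.arg(strategy)
  assert_two_classes(labelled)
  if (strategy != "certainty" && is.null(truth)) {
    stop("oracle strategies need ground-truth labels ('truth')", call. = FALSE)
  }
  if (length(intersect(rownames(labelled$table), rownames(pool$table)))) {
    stop("labelled and pool sample IDs must be disjoint", call. = FALSE)
  }
  if (normalize) {
    prep <- preprocess_dataset(labelled, pool, config$corr_cutoff)
    labelled <- prep$labelled
    pool <- prep$pool
  }

  total_n <- nrow(labelled$table) + nrow(pool$table)
  history <- list()
  assignments <- list()
  model <- NULL
  status <- "completed"
  alpha <- 1L

  repeat {
    frac <- nrow(labelled$table) / total_n
    if (frac >= config$stop_fraction || nrow(pool$table) == 0L) {
      status <- "completed"; break
    }
    if (alpha > config$max_iterations) {
      status <- "max_iter"; break
    }

    balanced <- smote_balance(labelled, config$smote_k,
                              derive_seed(config$seed, alpha, 1L))
    feats <- colnames(balanced$table)
    if (length(feats) > config$top_k_features) {
      rk <- select_top_features(balanced, config$top_k_features,
                                seed = derive_seed(config$seed, alpha, 2L))
      feats <- rk$selected
      balanced <- labelled_set(ft_subset(balanced$table, j = feats),
                               balanced$labels, balanced$provenance)
    }
    model <- train_classifier(balanced, config$classifier_params,
                              seed = derive_seed(config$seed, alpha, 3L),
                              cv_folds = config$cv_folds)
    scores <- predict(model, ft_subset(pool$table, j = feats))
    scored <- scored_pool(pool, scores)

    batch <- switch(strategy,
      certainty   = heuristic_select(scored, config$threshold, config$boundary),
      uncertainty = simulated_oracle(
        uncertainty_select(scored, config$batch_size, config$boundary), truth),
      random      = simulated_oracle(
        random_select(scored, config$batch_size,
                      derive_seed(config$seed, alpha, 4L), config$boundary),
        truth)
    )

    if (nrow(batch$samples) == 0L) {
      if (config$stall_fallback == "top1" && length(scores)) {
        ids <- c(names(which.max(scores)), names(which.min(scores)))
        ids <- unique(ids)
        batch$samples <- data.frame(
          sample_id = ids, score = unname(scores[ids]),
          pseudo_label = as.integer(scores[ids] >= config$boundary),
          stringsAsFactors = FALSE)
      } else {
        status <- "stalled"; break
      }
    }

    provenance <- if (strategy == "certainty") "pseudo" else "oracle"
    moved <- transfer_batch(labelled, pool, batch$samples$sample_id,
                            batch$samples$pseudo_label, provenance)
    labelled <- moved$labelled
    pool <- moved$pool

    cv <- model$cv_scores
    history[[alpha]] <- data.frame(
      alpha = alpha,
      sup = if (is.null(batch$sup)) NA_real_ else batch$sup,
      inf = if (is.null(batch$inf)) NA_real_ else batch$inf,
      n_selected = nrow(batch$samples),
      n_pos_selected = sum(batch$samples$pseudo_label == 1L),
      n_neg_selected = sum(batch$samples$pseudo_label == 0L),
      cv_accuracy = if (is.null(cv)) NA_real_ else cv[["accuracy"]],
      cv_precision = if (is.null(cv)) NA_real_ else cv[["precision"]],
      cv_roc_auc = if (is.null(cv)) NA_real_ else cv[["roc_auc"]],
      labelled_fraction = nrow(labelled$table) / total_n
    )
    assignments[[alpha]] <- data.frame(
      sample_id = batch$samples$sample_id,
      label = batch$samples$pseudo_label,
      score = batch$samples$score,
      iteration = alpha,
      provenance = provenance,
      stringsAsFactors = FALSE
    )
    alpha <- alpha + 1L
  }

  # refit the deployed classifier on the complete final labelled set (the
  # in-loop model only ever saw the state before the last batch)
  if (nrow(labelled$table) && length(unique(labelled$labels)) == 2L) {
    final_bal <- smote_balance(labelled, config$smote_k,
                               derive_seed(config$seed, alpha, 5L))
    final_feats <- colnames(final_bal$table)
    if (length(final_feats) > config$top_k_features) {
      final_feats <- select_top_features(final_bal, config$top_k_features,
                                         seed = derive_seed(config$seed, alpha, 6L))$selected
      final_bal <- labelled_set(ft_subset(final_bal$table, j = final_feats),
                                final_bal$labels, final_bal$provenance)
    }
    model <- train_classifier(final_bal, config$classifier_params,
                              seed = derive_seed(config$seed, alpha, 7L),
                              cv_folds = 0L)
  }

  structure(list(
    labelled = labelled,
    pool = pool,
    history = if (length(history)) do.call(rbind, history) else empty_history(),
    assignments = if (length(assignments)) do.call(rbind, assignments) else empty_assignments(),
    status = status,
    model = model,
    strategy = strategy,
    config = config,
    total_n = total_n
  ), class = "heal_result")
}

empty_history <- function() {
  data.frame(alpha = integer(), sup = numeric(), inf = numeric(),
             n_selected = integer(), n_pos_selected = integer(),
             n_neg_selected = integer(), cv_accuracy = numeric(),
             cv_precision = numeric(), cv_roc_auc = numeric(),
             labelled_fraction = numeric())
}

empty_assignments <- function() {
  data.frame(sample_id = character(), label = integer(), score = numeric(),
             iteration = integer(), provenance = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.heal_result <- function(x, ...) {
  cat(sprintf("<heal_result> strategy %s, status %s after %d iteration(s)\n",
              x$strategy, x$status, nrow(x$history)))
  cat(sprintf("  labelled %d / %d (%.1f%%), residual pool %d\n",
              nrow(x$labelled$table), x$total_n,
              100 * nrow(x$labelled$table) / x$total_n, nrow(x$pool$table)))
  invisible(x)
}

#' Benchmark one annotation strategy on a fully labelled data set
#'
#' The evaluation protocol: a stratified 20% of the data keeps its labels as
#' the seed set, the remaining 80% becomes the pool with its labels held
#' back, and the chosen strategy annotates the pool until the stop
#' criterion.  Certainty keeps its own pseudo-labels; uncertainty and random
#' sampling have each batch corrected by the simulated oracle.  Two metric
#' sets are reported and must not be conflated: `metrics_annotation`
#' compares every label assigned during the run against the held-back truth,
#' and `metrics_residual` evaluates the final classifier (thresholded at
#' `config$boundary`) on the residual pool.
#'
#' @param dataset A fully labelled [labelled_set()].
#' @param strategy `"certainty"`, `"uncertainty"` or `"random"`.
#' @param config A [heal_config()].
#' @param labelled_fraction Seed fraction for the split, default 0.2.
#' @return `list(result = <heal_result>, metrics_annotation, metrics_residual)`
#'   (metric entries are `NULL` when their sample set is empty).
#' @export
run_benchmark <- function(dataset, strategy = c("certainty", "uncertainty", "random"),
                          config = heal_config(), labelled_fraction = 0.2) {
  strategy <- match.arg(strategy)
  sp <- split_labelled_pool(dataset, labelled_fraction, config$seed)
  res <- run_active_loop(sp$labelled, sp$pool, config, strategy,
                         truth = sp$truth, normalize = TRUE)

  metrics_annotation <- NULL
  if (nrow(res$assignments)) {
    truth_assigned <- sp$truth[res$assignments$sample_id]
    metrics_annotation <- compute_metrics(res$assignments$label,
                                          res$assignments$score,
                                          truth_assigned)
  }

  metrics_residual <- NULL
  if (nrow(res$pool$table) && !is.null(res$model)) {
    scores <- predict(res$model, res$pool)
    truth_res <- sp$truth[rownames(res$pool$table)]
    metrics_residual <- compute_metrics(as.integer(scores >= config$boundary),
                                        scores, truth_res)
  }

  list(result = res, metrics_annotation = metrics_annotation,
       metrics_residual = metrics_residual)
}
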