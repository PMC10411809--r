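# Classifier training, metrics, the annotation loop and the benchmark
# harness

test_that("train_classifier separates clear blobs and fails on one class", {
  ds <- tiny_blobs(n = 100, sep = 3, seed = 61)
  clf <- train_classifier(ds, params = list(min_child_weight = 2), seed = 1,
                          cv_folds = 5)
  expect_gte(clf$cv_scores[["accuracy"]], 0.95)
  scores <- predict(clf, ds)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_gt(min(scores[ds$labels == 1L]), max(scores[ds$labels == 0L]))
  one_class <- labelled_set(matrix(rnorm(20), 10, 2), rep(1L, 10))
  expect_error(train_classifier(one_class), "both classes")
})

test_that("shuffled labels give chance-level cross-validated ROC-AUC", {
  set.seed(62)
  x <- matrix(rnorm(120 * 5), 120, 5)
  y <- sample(rep(0:1, 60))
  clf <- train_classifier(labelled_set(x, y),
                          params = list(min_child_weight = 2), seed = 2)
  expect_lt(abs(clf$cv_scores[["roc_auc"]] - 0.5), 0.1)
})

test_that("compute_metrics matches hand counts and handles edge cases", {
  m <- compute_metrics(c(1, 1, 0, 0), truth = c(1, 0, 0, 0))
  expect_equal(c(m$TP, m$FP, m$TN, m$FN), c(1, 1, 2, 0))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 0.5)
  perfect <- compute_metrics(c(1, 0, 1), c(0.9, 0.1, 0.8), c(1, 0, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$roc_auc, 1)
  anti <- compute_metrics(c(0, 1), c(0.9, 0.1), c(0, 1))
  expect_equal(anti$roc_auc, 0)
  # no positive predictions -> precision absent; single-class truth -> AUC absent
  expect_true(is.na(compute_metrics(c(0, 0), truth = c(1, 0))$precision))
  expect_true(is.na(compute_metrics(c(1, 1), c(0.2, 0.8), c(1, 1))$roc_auc))
})

test_that("rank-statistic ROC-AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(63)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    truth <- sample(0:1, n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- round(runif(n), 2)   # ties included
    got <- compute_metrics(as.integer(scores >= 0.5), scores, truth)$roc_auc
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(truth, scores, direction = "<", quiet = TRUE))))
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("simulated_oracle restores ground truth and validates coverage", {
  sc <- scored_pool(pool(matrix(0, 3, 1, dimnames = list(c("a", "b", "c"), "f"))),
                    c(a = 0.9, b = 0.1, c = 0.7))
  batch <- uncertainty_select(sc, batch_size = 3)
  truth <- c(a = 0L, b = 1L, c = 0L)     # oracle disagrees with all pre-labels
  fixed <- simulated_oracle(batch, truth)
  expect_identical(stats::setNames(fixed$samples$pseudo_label, fixed$samples$sample_id)[names(truth)],
                   truth)
  expect_error(simulated_oracle(batch, truth[1:2]), "missing")
  empty <- batch; empty$samples <- batch$samples[0, ]
  expect_identical(nrow(simulated_oracle(empty, truth)$samples), 0L)
})

test_that("run_heal completes on separable data with faithful pseudo-labels", {
  ds <- make_binary_dataset(synth_spec(n_samples = 200, class_sep = 3, seed = 71))
  sp <- split_labelled_pool(ds, 0.2, seed = 71)
  res <- run_heal(sp$labelled, sp$pool, desk_config(seed = 71))
  expect_equal(res$status, "completed")
  expect_gte(nrow(res$labelled$table) / res$total_n, 0.9)
  expect_gte(assignment_agreement(res, sp$truth), 0.95)
  expect_true(all(res$assignments$provenance == "pseudo"))
})

test_that("empty initial pool returns immediately as completed", {
  ds <- tiny_blobs(n = 30, seed = 72)
  empty_pool <- pool(matrix(numeric(), 0, ncol(ds$table),
                            dimnames = list(NULL, colnames(ds$table))))
  res <- run_heal(ds, empty_pool, desk_config(), normalize = FALSE)
  expect_equal(res$status, "completed")
  expect_equal(nrow(res$history), 0)
})

test_that("a pool the heuristic cannot touch stalls the loop", {
  # all pool scores will sit in [boundary, threshold): P- empty and no
  # positive can clear sup >= 0.9 if the classifier is uninformative.
  # Force this with the large-data hessian floor, which yields a constant
  # 0.5 score: boundary 0.4 puts everything in P+ with 0.5 < threshold.
  ds <- tiny_blobs(n = 40, seed = 73)
  sp_pool <- pool(matrix(rnorm(40 * ncol(ds$table)), 40, ncol(ds$table),
                         dimnames = list(paste0("p", 1:40),
                                         colnames(ds$table))))
  cfg <- heal_config(boundary = 0.4, threshold = 0.9, cv_folds = 0,
                     classifier_params = list(min_child_weight = 40), seed = 1)
  res <- run_heal(ds, sp_pool, cfg, normalize = FALSE)
  expect_equal(res$status, "stalled")
  expect_equal(nrow(res$history), 0)
  # the top1 fallback makes progress instead
  cfg2 <- heal_config(boundary = 0.4, threshold = 0.9, cv_folds = 0,
                      classifier_params = list(min_child_weight = 40), seed = 1,
                      stall_fallback = "top1")
  res2 <- run_heal(ds, sp_pool, cfg2, normalize = FALSE)
  expect_gt(nrow(res2$labelled$table), nrow(ds$table))
})

test_that("loop conserves samples, never relabels, and labels monotonically", {
  ds <- make_binary_dataset(synth_spec(n_samples = 150, class_sep = 2, seed = 74))
  sp <- split_labelled_pool(ds, 0.2, seed = 74)
  res <- run_heal(sp$labelled, sp$pool, desk_config(seed = 74))
  expect_equal(nrow(res$labelled$table) + nrow(res$pool$table), res$total_n)
  expect_false(anyDuplicated(res$assignments$sample_id) > 0)
  expect_false(any(res$assignments$sample_id %in% rownames(sp$labelled$table)))
  h <- res$history
  expect_identical(h$alpha, seq_len(nrow(h)))
  expect_true(all(diff(h$labelled_fraction) > 0))
  expect_equal(h$n_selected, h$n_pos_selected + h$n_neg_selected)
  # certainty-threshold soundness at assignment time
  pos <- res$assignments[res$assignments$label == 1L, ]
  expect_true(all(pos$score >= 0.9))
})

test_that("oracle strategies assign only ground-truth labels and hit the stop rule", {
  ds <- make_binary_dataset(synth_spec(n_samples = 150, class_sep = 2, seed = 75))
  for (strat in c("uncertainty", "random")) {
    bm <- run_benchmark(ds, strat, desk_config(seed = 75))
    a <- bm$result$assignments
    sp_truth <- split_labelled_pool(ds, 0.2, seed = 75)$truth
    expect_identical(a$label, unname(sp_truth[a$sample_id]))
    expect_true(all(a$provenance == "oracle"))
    expect_gte(nrow(bm$result$labelled$table) / bm$result$total_n, 0.9)
    expect_equal(bm$metrics_annotation$accuracy, 1)
    # benchmark batches obey the configured size (except the final remainder)
    h <- bm$result$history
    expect_true(all(h$n_selected[-nrow(h)] == 20))
  }
})

test_that("per-iteration CV scores are recorded when requested", {
  ds <- make_binary_dataset(synth_spec(n_samples = 120, class_sep = 3, seed = 76))
  sp <- split_labelled_pool(ds, 0.25, seed = 76)
  cfg <- heal_config(seed = 76, classifier_params = list(min_child_weight = 2),
                     cv_folds = 5)
  res <- run_heal(sp$labelled, sp$pool, cfg)
  expect_true(all(is.finite(res$history$cv_accuracy)))
  expect_true(all(res$history$cv_roc_auc >= 0 & res$history$cv_roc_auc <= 1))
})
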