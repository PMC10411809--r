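# Normalisation, redundancy filtering, SMOTE and permutation-importance
# feature selection

test_that("zscore_normalize standardises columns and zeroes constant ones", {
  ft <- feature_table(cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(-1, 0, 1)))
  z <- zscore_normalize(ft)
  expect_equal(unname(unclass(z)[, "a"]), c(-1, 0, 1))
  expect_equal(unname(unclass(z)[, "b"]), c(0, 0, 0))
  # idempotent on already-standardised input
  expect_equal(unclass(zscore_normalize(z)), unclass(z), tolerance = 1e-12)
  expect_error(zscore_normalize(feature_table(matrix(1, 1, 2))), "at least 2")
})

test_that("zscore output has mean 0 and sample sd 1 on non-constant columns", {
  set.seed(8)
  z <- unclass(zscore_normalize(feature_table(matrix(rnorm(200, 5, 3), 50, 4))))
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
})

test_that("correlation_filter keeps the most target-correlated member of a group", {
  set.seed(2)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  base <- rnorm(n) + 2 * y
  # three features pairwise correlated ~0.95+, with distinct target correlations
  f1 <- base + rnorm(n, 0, 0.22)
  f2 <- base + rnorm(n, 0, 0.30)
  f3 <- base + rnorm(n, 0, 0.05)      # closest to base -> highest |r to target|
  noise <- rnorm(n)
  ft <- feature_table(cbind(f1 = f1, f2 = f2, f3 = f3, noise = noise))
  stopifnot(min(abs(cor(cbind(f1, f2, f3)))) > 0.9)
  res <- correlation_filter(ft, y, r_cut = 0.70)
  kept <- colnames(res$table)
  # brute-force: retained set must have no pair above the cut
  rk <- cor(unclass(res$table))
  expect_true(all(abs(rk[upper.tri(rk)]) <= 0.70))
  # and must keep the arg-max target-correlation member of the group
  r_t <- abs(cor(cbind(f1, f2, f3), y))
  expect_true(c("f1", "f2", "f3")[which.max(r_t)] %in% kept)
  expect_length(intersect(kept, c("f1", "f2", "f3")), 1)
  expect_true("noise" %in% kept)
  expect_setequal(res$dropped$feature, setdiff(c("f1", "f2", "f3"), kept))
})

test_that("correlation_filter: identical copies collapse to one; independents survive", {
  set.seed(3)
  x <- rnorm(50)
  ft <- feature_table(cbind(a = x, b = x, c = rnorm(50)))
  res <- correlation_filter(ft, rep(0:1, 25), r_cut = 0.70)
  expect_length(intersect(colnames(res$table), c("a", "b")), 1)
  ft2 <- feature_table(matrix(rnorm(300), 100, 3))
  res2 <- correlation_filter(ft2, rep(0:1, 50), r_cut = 0.70)
  expect_equal(ncol(res2$table), 3)
  expect_equal(nrow(res2$dropped), 0)
})

test_that("correlation_filter result is invariant to column order", {
  set.seed(4)
  n <- 150; y <- rep(0:1, each = n / 2)
  base <- rnorm(n) + 1.5 * y
  m <- cbind(p = base + rnorm(n, 0, 0.2), q = base + rnorm(n, 0, 0.4),
             r = rnorm(n))
  kept1 <- colnames(correlation_filter(feature_table(m), y)$table)
  kept2 <- colnames(correlation_filter(feature_table(m[, c(3, 2, 1)]), y)$table)
  expect_setequal(kept1, kept2)
})

test_that("zero-variance features are never removed by the correlation filter", {
  ft <- feature_table(cbind(const = rep(2, 30), x = rnorm(30)))
  res <- correlation_filter(ft, rep(0:1, 15))
  expect_true("const" %in% colnames(res$table))
})

test_that("smote_balance equalises counts without touching original rows", {
  ds <- tiny_blobs(n = 50, pos_frac = 0.2, seed = 6)   # 10 positives / 40 negatives
  bal <- smote_balance(ds, seed = 9)
  expect_equal(sum(bal$labels == 1L), 40)
  expect_equal(sum(bal$labels == 0L), 40)
  orig_ids <- rownames(ds$table)
  expect_identical(unclass(bal$table)[orig_ids, ], unclass(ds$table)[orig_ids, ])
  expect_identical(bal$labels[orig_ids], ds$labels[orig_ids])
  synth <- setdiff(rownames(bal$table), orig_ids)
  expect_length(synth, 30)
  expect_true(all(bal$provenance[synth] == "synthetic"))
  expect_true(all(bal$labels[synth] == 1L))
})

test_that("every SMOTE point lies on a segment between two minority originals", {
  ds <- tiny_blobs(n = 40, pos_frac = 0.25, seed = 7)
  bal <- smote_balance(ds, k_neighbors = 5, seed = 13)
  xm <- unclass(ds$table)[ds$labels == 1L, , drop = FALSE]
  synth <- unclass(bal$table)[bal$provenance == "synthetic", , drop = FALSE]
  on_segment <- function(p) {
    for (i in seq_len(nrow(xm) - 1)) for (j in seq(i + 1, nrow(xm))) {
      v <- xm[j, ] - xm[i, ]
      u <- if (sum(v^2) == 0) 0 else sum((p - xm[i, ]) * v) / sum(v^2)
      if (u > -1e-9 && u < 1 + 1e-9 &&
          sqrt(sum((xm[i, ] + u * v - p)^2)) < 1e-8) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, on_segment)))
})

test_that("smote_balance degenerate inputs behave per contract", {
  bal <- tiny_blobs(n = 20, pos_frac = 0.5, seed = 2)
  expect_identical(smote_balance(bal, seed = 1), bal)  # already balanced
  one_min <- labelled_set(matrix(rnorm(10), 5, 2), c(1, 0, 0, 0, 0))
  expect_error(smote_balance(one_min, seed = 1), "at least 2 minority")
  # minority count <= k: neighbours capped, still balances
  few <- tiny_blobs(n = 33, pos_frac = 0.1, seed = 3)  # 3 positives
  b <- smote_balance(few, k_neighbors = 5, seed = 4)
  expect_equal(sum(b$labels == 1L), sum(b$labels == 0L))
})

test_that("select_top_features caps at n_features and is seed-deterministic", {
  ds <- tiny_blobs(n = 80, d = 6, seed = 10)
  rk <- select_top_features(ds, k = 400, seed = 5)
  expect_length(rk$selected, 6)
  expect_equal(nrow(rk$ranking), 6)
  expect_true(all(diff(rk$ranking$importance) <= 0))
  rk2 <- select_top_features(ds, k = 400, seed = 5)
  expect_identical(rk$ranking, rk2$ranking)
  expect_identical(rk$selected[1:3],
                   select_top_features(ds, k = 3, seed = 5)$selected)
})

test_that("permutation importance finds the predictive feature among noise", {
  hits <- 0; noise_imps <- c()
  for (s in 1:50) {
    set.seed(s)
    n <- 80
    x <- matrix(rnorm(n * 21), n, 21,
                dimnames = list(NULL, c("signal", paste0("n", 1:20))))
    y <- as.integer(x[, "signal"] + rnorm(n, 0, 0.4) > 0)
    rk <- select_top_features(labelled_set(x, y), k = 21, n_trees = 60, seed = s)
    if (rk$ranking$feature[1] == "signal") hits <- hits + 1
    noise_imps <- c(noise_imps,
                    rk$ranking$importance[rk$ranking$feature != "signal"])
  }
  expect_gte(hits / 50, 0.95)
  # pure-noise importances straddle zero
  se <- sd(noise_imps) / sqrt(length(noise_imps))
  expect_lt(abs(mean(noise_imps)), 2 * se + 1e-3)
})

test_that("preprocess_dataset fits once on the union and keeps IDs intact", {
  ds <- make_binary_dataset(synth_spec(n_samples = 80, n_features = 8,
                                       n_informative = 3, n_redundant = 2,
                                       rho = 0.95, seed = 21))
  sp <- split_labelled_pool(ds, 0.25, seed = 21)
  prep <- preprocess_dataset(sp$labelled, sp$pool, corr_cutoff = 0.70)
  expect_identical(rownames(prep$labelled$table), rownames(sp$labelled$table))
  expect_identical(rownames(prep$pool$table), rownames(sp$pool$table))
  expect_identical(colnames(prep$labelled$table), colnames(prep$pool$table))
  # redundant copies (rho = 0.95 > 0.70) must trigger drops
  expect_gt(nrow(prep$dropped), 0)
  union_z <- rbind(unclass(prep$labelled$table), unclass(prep$pool$table))
  expect_true(all(abs(colMeans(union_z)) < 1e-9))
})
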