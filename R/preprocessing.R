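#' Z-score normalise a feature table
#'
#' Each column is centred and scaled to unit sample standard deviation
#' (denominator n-1).  Constant columns carry no information and are mapped
#' to all-zeros rather than NaN.
#'
#' @param table A [feature_table()] with at least 2 rows.
#' @return The normalised [feature_table()].
#' @export
zscore_normalize <- function(table) {
  table <- as_feature_table(table)
  if (nrow(table) < 2L) stop("need at least 2 samples to z-score", call. = FALSE)
  m <- unclass(table)
  mu <- colMeans(m)
  sd_ <- apply(m, 2, stats::sd)
  out <- sweep(m, 2, mu, "-")
  nz <- sd_ > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sd_[nz], "/")
  out[, !nz] <- 0
  feature_table(out)
}

#' Remove highly correlated (redundant) features
#'
#' Drops features so that no retained pair has |Pearson r| above `r_cut`.
#' Pairs are examined in descending |r| order; whenever both members of an
#' offending pair are still retained, the one with the lower |correlation
#' with the target labels| is dropped (ties keep the earlier column).  This
#' realises the rule "keep the feature most correlated with the target" as a
#' deterministic greedy pass.
#'
#' Zero-variance features have undefined correlations; they are treated as
#' r = 0 everywhere and are therefore never removed by this filter.
#'
#' @param table A [feature_table()].
#' @param target Binary labels for the rows used to compute target
#'   correlations.  May cover a subset of rows (give a named 0/1 vector whose
#'   names are sample IDs); unlabelled rows are then ignored for the
#'   keep-choice but still count toward pairwise correlations.
#' @param r_cut Redundancy cutoff on |Pearson r|, default 0.70.
#' @return `list(table = <feature_table of retained columns>,
#'   dropped = <data.frame feature/partner/r>)`.
#' @export
correlation_filter <- function(table, target, r_cut = 0.70) {
  table <- as_feature_table(table)
  m <- unclass(table)
  p <- ncol(m)
  if (p < 2L) return(list(table = table, dropped = empty_dropped()))

  if (!is.null(names(target))) {
    rows <- intersect(rownames(m), names(target))
    tgt <- as.numeric(target[rows])
    tgt_rows <- rows
  } else {
    if (length(target) != nrow(m)) {
      stop("'target' must be named by sample ID or align with table rows",
           call. = FALSE)
    }
    tgt <- as.numeric(target)
    tgt_rows <- rownames(m)
  }

  cors <- suppressWarnings(stats::cor(m))
  cors[!is.finite(cors)] <- 0
  r_target <- suppressWarnings(
    as.numeric(stats::cor(m[tgt_rows, , drop = FALSE], tgt))
  )
  r_target[!is.finite(r_target)] <- 0

  ut <- which(upper.tri(cors) & abs(cors) > r_cut, arr.ind = TRUE)
  if (!nrow(ut)) return(list(table = table, dropped = empty_dropped()))
  r_abs <- abs(cors[ut])
  ord <- order(-r_abs, ut[, 1], ut[, 2])
  ut <- ut[ord, , drop = FALSE]

  retained <- rep(TRUE, p)
  dropped <- vector("list", nrow(ut))
  for (k in seq_len(nrow(ut))) {
    i <- ut[k, 1]; j <- ut[k, 2]
    if (!(retained[i] && retained[j])) next
    # drop the member less correlated with the target; ties keep column i (earlier)
    loser <- if (abs(r_target[j]) - abs(r_target[i]) > 1e-15) i else j
    retained[loser] <- FALSE
    dropped[[k]] <- data.frame(
      feature = colnames(m)[loser],
      partner = colnames(m)[if (loser == i) j else i],
      r = cors[i, j],
      stringsAsFactors = FALSE
    )
  }
  dropped <- do.call(rbind, dropped[!vapply(dropped, is.null, logical(1))])
  if (is.null(dropped)) dropped <- empty_dropped()
  list(table = ft_subset(table, j = which(retained)), dropped = dropped)
}

empty_dropped <- function() {
  data.frame(feature = character(), partner = character(), r = numeric(),
             stringsAsFactors = FALSE)
}

#' Balance classes by synthetic minority oversampling (SMOTE)
#'
#' Generates synthetic minority-class samples until both classes have equal
#' counts.  Each synthetic point is a convex combination
#' `x + u * (x_nn - x)`, `u ~ U(0,1)`, of a real minority sample `x` and one
#' of its `k_neighbors` nearest minority-class neighbours (Euclidean
#' distance).  Original rows are never modified or deleted; synthetic rows
#' are tagged `provenance = "synthetic"`.
#'
#' @param labelled A [labelled_set()] containing both classes.
#' @param k_neighbors Number of minority nearest neighbours considered,
#'   default 5; capped at (minority count - 1) when the minority class is
#'   small.
#' @param seed Integer seed making the oversampling deterministic.
#' @return A balanced [labelled_set()]; returned unchanged when the input is
#'   already balanced.
#' @export
smote_balance <- function(labelled, k_neighbors = 5L, seed = 1L) {
  assert_two_classes(labelled)
  counts <- table(factor(labelled$labels, levels = c(0L, 1L)))
  if (counts[1] == counts[2]) return(labelled)
  minority <- as.integer(names(which.min(counts)))
  n_min <- min(counts); n_maj <- max(counts)
  if (n_min < 2L) {
    stop("SMOTE needs at least 2 minority samples (no neighbour exists)",
         call. = FALSE)
  }
  k <- min(as.integer(k_neighbors), n_min - 1L)
  m <- unclass(labelled$table)
  min_idx <- which(labelled$labels == minority)
  xm <- m[min_idx, , drop = FALSE]
  # k nearest minority neighbours of each minority sample (excluding itself)
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- apply(d, 1, function(row) order(row)[seq_len(k)])  # k x n_min
  if (is.null(dim(nn))) nn <- matrix(nn, nrow = 1L)
  nn <- t(nn)                                              # n_min x k
  need <- n_maj - n_min
  synth <- with_seed(seed, {
    base <- sample.int(n_min, need, replace = TRUE)
    pick <- sample.int(k, need, replace = TRUE)
    u <- stats::runif(need)
    xa <- xm[base, , drop = FALSE]
    xb <- xm[nn[cbind(base, pick)], , drop = FALSE]
    xa + u * (xb - xa)
  })
  rownames(synth) <- make.unique(c(rownames(m), paste0("synth_", seq_len(need))),
                                 sep = "_")[nrow(m) + seq_len(need)]
  labelled_set(
    rbind(m, synth),
    c(labelled$labels, rep(minority, need)),
    c(labelled$provenance, rep("synthetic", need))
  )
}

#' Rank features by out-of-bag permutation importance
#'
#' Fits a random forest (each tree bootstrap-initialised) on the labelled
#' set, estimates a baseline score on the out-of-bag samples, then for each
#' feature permutes its values and scores again; the importance of a feature
#' is the baseline score minus the permuted score (mean decrease in OOB
#' accuracy).  Features are ranked by descending importance and the top
#' `min(k, n_features)` form the selected panel.
#'
#' @param labelled A trainable [labelled_set()] (both classes present).
#' @param k Size of the selected panel, default 400.
#' @param n_trees Trees in the forest, default 100.
#' @param seed Integer seed.
#' @return Object of class `"feature_ranking"`: `list(ranking =
#'   <data.frame feature/importance, descending>, selected = <character
#'   vector of the top min(k, p) feature names>)`.
#' @export
select_top_features <- function(labelled, k = 400L, n_trees = 100L, seed = 1L) {
  assert_two_classes(labelled)
  m <- unclass(labelled$table)
  y <- factor(labelled$labels, levels = c(0L, 1L))
  rf <- with_seed(seed, {
    randomForest::randomForest(m, y, ntree = n_trees, importance = TRUE)
  })
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  ord <- order(-imp)           # stable: ties keep column order
  ranking <- data.frame(feature = colnames(m)[ord],
                        importance = unname(imp[ord]),
                        stringsAsFactors = FALSE)
  selected <- ranking$feature[seq_len(min(as.integer(k), ncol(m)))]
  structure(list(ranking = ranking, selected = selected),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %d features ranked, %d selected\n",
              nrow(x$ranking), length(x$selected)))
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' One-off preprocessing of a labelled set and pool
#'
#' Applies the global stages that are fit once on the union of labelled and
#' pool feature values: z-score normalisation and the Pearson redundancy
#' filter (labels are used only to choose which member of a correlated group
#' to keep).  Per-iteration stages (SMOTE, permutation-importance selection)
#' live inside the annotation loop.
#'
#' @param labelled A [labelled_set()].
#' @param pool A [pool()] sharing the same feature columns.
#' @param corr_cutoff Redundancy cutoff, default 0.70; `NULL` skips the
#'   filter.
#' @return `list(labelled, pool, dropped)`.
#' @export
preprocess_dataset <- function(labelled, pool, corr_cutoff = 0.70) {
  stopifnot(identical(colnames(labelled$table), colnames(pool$table)))
  union_tab <- feature_table(rbind(unclass(labelled$table), unclass(pool$table)))
  norm <- zscore_normalize(union_tab)
  dropped <- empty_dropped()
  if (!is.null(corr_cutoff)) {
    flt <- correlation_filter(norm, labelled$labels, r_cut = corr_cutoff)
    norm <- flt$table
    dropped <- flt$dropped
  }
  lab_ids <- rownames(labelled$table)
  pool_ids <- rownames(pool$table)
  list(
    labelled = labelled_set(ft_subset(norm, lab_ids),
                            labelled$labels, labelled$provenance),
    pool = pool(ft_subset(norm, pool_ids)),
    dropped = dropped
  )
}
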