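#' Attach classifier scores to a pool
#'
#' @param pool A [pool()].
#' @param scores Numeric vector of positive-class probabilities in `[0,1]`,
#'   one per pool sample (aligned with the pool rows, or named by sample ID).
#' @return Object of class `"scored_pool"`.
#' @export
scored_pool <- function(pool, scores) {
  ids <- rownames(pool$table)
  if (!is.null(names(scores))) {
    if (!setequal(names(scores), ids)) {
      stop("score names must match the pool sample IDs", call. = FALSE)
    }
    scores <- scores[ids]
  } else if (length(scores) != length(ids)) {
    stop("need exactly one score per pool sample", call. = FALSE)
  }
  scores <- as.numeric(scores)
  if (any(is.na(scores)) || any(scores < 0) || any(scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  structure(list(pool = pool, score = stats::setNames(scores, ids)),
            class = "scored_pool")
}

#' @export
print.scored_pool <- function(x, ...) {
  cat(sprintf("<scored_pool> %d samples, score range [%.3f, %.3f]\n",
              length(x$score),
              if (length(x$score)) min(x$score) else NA,
              if (length(x$score)) max(x$score) else NA))
  invisible(x)
}

#' Partition pool scores at the classification boundary
#'
#' Splits the scored pool into the provisional-positive distribution
#' (scores at or above `boundary`) and the provisional-negative distribution
#' (the rest).  With the default boundary 0.6 these are the score ranges
#' 0.6-1.0 and 0.0-0.59... of the automatic annotation.
#'
#' @param scored A [scored_pool()] (may be empty).
#' @param boundary Classification boundary, default 0.6.
#' @return `list(p_plus = <named scores>, p_minus = <named scores>)`; an
#'   exact partition of the pool scores.
#' @export
partition_by_boundary <- function(scored, boundary = 0.6) {
  s <- scored$score
  list(p_plus = s[s >= boundary], p_minus = s[s < boundary])
}

#' Quartile of a score distribution by the (i/4)(n+1)-th-term rule
#'
#' Returns the order statistic at position `(i/4) * (n + 1)`; fractional
#' positions are linearly interpolated between adjacent order statistics and
#' positions outside `[1, n]` are clamped to the extremes (so `i = 4` on
#' n values returns the maximum).  This is the Tukey-style plotting position
#' also implemented by `stats::quantile(type = 6)`.
#'
#' @param values Non-empty numeric vector (any order).
#' @param i Quartile index 1-4.
#' @return The interpolated quartile value.
#' @export
heal_quartile <- function(values, i) {
  if (!length(values)) stop("cannot take a quartile of an empty set", call. = FALSE)
  if (!(i %in% 1:4)) stop("'i' must be a quartile index 1-4", call. = FALSE)
  v <- sort(values)
  n <- length(v)
  pos <- min(max((i / 4) * (n + 1), 1), n)
  lo <- floor(pos); hi <- ceiling(pos)
  v[lo] + (pos - lo) * (v[hi] - v[lo])
}

new_selected_batch <- function(ids, scores, labels, sup, inf, strategy) {
  structure(list(
    samples = data.frame(sample_id = ids, score = unname(scores),
                         pseudo_label = as.integer(labels),
                         stringsAsFactors = FALSE),
    sup = sup, inf = inf, strategy = strategy
  ), class = "selected_batch")
}

#' @export
print.selected_batch <- function(x, ...) {
  cat(sprintf("<selected_batch> strategy %s: %d samples (%d positive / %d negative)\n",
              x$strategy, nrow(x$samples),
              sum(x$samples$pseudo_label == 1L), sum(x$samples$pseudo_label == 0L)))
  cat(sprintf("  cut-offs: sup = %s, inf = %s\n",
              format(x$sup), format(x$inf)))
  invisible(x)
}

#' Certainty-sampling heuristic selection with dynamic quartile cut-offs
#'
#' The heuristic component that replaces the human oracle.  The scored pool
#' is split at `boundary` into provisional positives `P+` and negatives
#' `P-`.  On the positive side the third quartile of `P+` defines the
#' fourth-quartile members (scores at or above Q3); the dynamic upper
#' cut-off is `sup = min(Q4 members)` when that minimum exceeds the user
#' `threshold`, else `sup = threshold`, and every sample scoring at or above
#' `sup` is pseudo-labelled positive.  On the negative side the first
#' quartile of `P-` defines its members (scores at or below Q1) and the
#' cut-off is `inf = max(Q1 members)`; samples scoring at or below `inf`
#' are pseudo-labelled negative.  No user threshold applies on the negative
#' side — the asymmetry is deliberate.  The batch is the union of both sides
#' and may be empty.
#'
#' Every selected positive necessarily satisfies `score >= threshold`, since
#' `sup >= threshold` always.
#'
#' @param scored A [scored_pool()].
#' @param threshold User confidence threshold (floor for `sup`), default
#'   0.9.
#' @param boundary Classification boundary, default 0.6.
#' @return A `selected_batch` with `strategy = "certainty"`, recording the
#'   `sup` and `inf` cut-offs used (`inf` is `NA` when `P-` is empty).
#' @export
heuristic_select <- function(scored, threshold = 0.9, boundary = 0.6) {
  parts <- partition_by_boundary(scored, boundary)
  p_plus <- parts$p_plus; p_minus <- parts$p_minus

  sup <- threshold
  pos <- p_plus[0]
  if (length(p_plus)) {
    q3 <- heal_quartile(p_plus, 3)
    q4_members <- p_plus[p_plus >= q3]
    if (min(q4_members) > threshold) sup <- min(q4_members)
    pos <- p_plus[p_plus >= sup]
  }

  inf <- NA_real_
  neg <- p_minus[0]
  if (length(p_minus)) {
    q1 <- heal_quartile(p_minus, 1)
    q1_members <- p_minus[p_minus <= q1]
    inf <- max(q1_members)
    neg <- p_minus[p_minus <= inf]
  }

  ids <- c(names(pos), names(neg))
  scores <- c(pos, neg)
  labels <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  ord <- order(ids)  # ascending sample ID for reproducibility
  new_selected_batch(ids[ord], scores[ord], labels[ord], sup, inf, "certainty")
}

#' Uncertainty sampling: the batch closest to the decision boundary
#'
#' The classical query strategy of the benchmark: selects the `batch_size`
#' pool samples minimising `|score - boundary|` (ties broken by ascending
#' sample ID).  Pre-labels are set from the score side of the boundary and
#' are meant to be corrected by an oracle (see [simulated_oracle()]).
#'
#' @param scored A non-empty [scored_pool()].
#' @param batch_size Batch size, default 20; the whole pool when smaller.
#' @param boundary Classification boundary, default 0.6.
#' @return A `selected_batch` with `strategy = "uncertainty"`.
#' @export
uncertainty_select <- function(scored, batch_size = 20L, boundary = 0.6) {
  s <- scored$score
  if (!length(s)) stop("cannot select from an empty pool", call. = FALSE)
  ord <- order(abs(s - boundary), names(s))
  take <- ord[seq_len(min(batch_size, length(s)))]
  new_selected_batch(names(s)[take], s[take],
                     as.integer(s[take] >= boundary),
                     NA_real_, NA_real_, "uncertainty")
}

#' Random sampling: a uniform batch from the pool
#'
#' The second benchmark strategy: a uniform sample without replacement of
#' `min(batch_size, pool size)` samples, deterministic given `seed`.
#' Pre-labels are set from the score side of the boundary for oracle
#' correction.
#'
#' @param scored A non-empty [scored_pool()].
#' @param batch_size Batch size, default 20.
#' @param seed Integer seed.
#' @param boundary Classification boundary, default 0.6.
#' @return A `selected_batch` with `strategy = "random"`.
#' @export
random_select <- function(scored, batch_size = 20L, seed = 1L, boundary = 0.6) {
  s <- scored$score
  if (!length(s)) stop("cannot select from an empty pool", call. = FALSE)
  take <- with_seed(seed, sample(names(s), min(batch_size, length(s))))
  take <- sort(take)
  new_selected_batch(take, s[take], as.integer(s[take] >= boundary),
                     NA_real_, NA_real_, "random")
}
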