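# Independent oracles and small fixture builders shared across tests.
# Oracles are written directly from the definitions and deliberately avoid
# the package's own code paths.

# Brute-force certainty selection: quartiles via stats::quantile(type = 6)
# (the (n+1)p plotting position), candidates enumerated from the definition.
oracle_certainty <- function(scores, threshold = 0.9, boundary = 0.6) {
  p_plus <- scores[scores >= boundary]
  p_minus <- scores[scores < boundary]
  sup <- threshold
  pos <- character()
  if (length(p_plus)) {
    q3 <- unname(stats::quantile(p_plus, 0.75, type = 6))
    members <- p_plus[p_plus >= q3]
    if (min(members) > threshold) sup <- min(members)
    pos <- names(p_plus)[p_plus >= sup]
  }
  inf <- NA_real_
  neg <- character()
  if (length(p_minus)) {
    q1 <- unname(stats::quantile(p_minus, 0.25, type = 6))
    members <- p_minus[p_minus <= q1]
    inf <- max(members)
    neg <- names(p_minus)[p_minus <= inf]
  }
  list(pos = sort(pos), neg = sort(neg), sup = sup, inf = inf)
}

# Exhaustive maximum-weight independent set over all 2^n subsets via a
# bitmask dynamic programme (n <= 18).  Returns the optimal total weight.
oracle_mwis_weight <- function(adj_masks, w) {
  n <- length(w)
  N <- 2L^n
  ok <- logical(N); ok[1] <- TRUE
  wt <- numeric(N)
  for (s in seq_len(N - 1L)) {
    lbv <- bitwAnd(s, -s)
    i <- as.integer(round(log2(lbv))) + 1L
    rest <- s - lbv
    ok[s + 1L] <- ok[rest + 1L] && bitwAnd(adj_masks[i], rest) == 0L
    wt[s + 1L] <- wt[rest + 1L] + w[i]
  }
  max(wt[ok])
}

# random graph as (edges matrix over ids, bitmasks, weights)
random_graph_sets <- function(n, p_edge, seed) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n))
  w <- 1 - log10(10^stats::runif(n, -10, 0)) / 100
  adj_masks <- integer(n)
  edges <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (stats::runif(1) < p_edge) {
        edges[[length(edges) + 1L]] <- c(i, j)
        adj_masks[i] <- bitwOr(adj_masks[i], as.integer(2^(j - 1)))
        adj_masks[j] <- bitwOr(adj_masks[j], as.integer(2^(i - 1)))
      }
    }
  }
  list(ids = ids, w = w, adj_masks = adj_masks,
       edges = if (length(edges)) do.call(rbind, edges) else matrix(integer(), 0, 2))
}

# hypergeometric tail by direct enumeration: P(overlap >= a) for a list of
# size l and a set of size s in a universe of size N
oracle_hyper_tail <- function(a, l, s, N) {
  js <- a:min(l, s)
  sum(stats::dhyper(js, s, N - s, l))
}

# tiny deterministic labelled set: two shifted Gaussian blobs
tiny_blobs <- function(n = 60, d = 4, sep = 3, pos_frac = 0.5, seed = 1) {
  set.seed(seed)
  n_pos <- round(n * pos_frac)
  y <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  x <- matrix(rnorm(n * d), n, d)
  x[y == 1L, ] <- x[y == 1L, ] + sep
  dimnames(x) <- list(paste0("t", seq_len(n)), paste0("f", seq_len(d)))
  labelled_set(x, y)
}

# desk-scale configuration used throughout the simulations: the printed
# large-data hyperparameters except the leaf hessian floor, which forbids
# any split below a few hundred rows (see the methods vignette)
desk_config <- function(seed = 1L, ...) {
  heal_config(seed = seed, classifier_params = list(min_child_weight = 2),
              cv_folds = 0L, ...)
}

# agreement of assigned labels with held-back truth
assignment_agreement <- function(bench_or_result, truth = NULL) {
  res <- if (inherits(bench_or_result, "heal_result")) bench_or_result
         else bench_or_result$result
  a <- res$assignments
  if (!nrow(a)) return(NA_real_)
  if (is.null(truth)) stop("need truth labels")
  mean(a$label == truth[a$sample_id])
}
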