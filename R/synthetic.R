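#' Specification of a synthetic two-class tabular data set
#'
#' Describes the Gaussian two-cluster structure the annotation method
#' assumes: `n_informative` dimensions whose class means differ by
#' `class_sep` standard deviations each, pure-noise dimensions, and
#' optional redundant dimensions correlated at about `rho` with an
#' informative source (these exercise the correlation filter).
#'
#' @param n_samples Total samples, default 200.
#' @param n_features Total features, default 10.
#' @param n_informative Informative dimensions, default 5.
#' @param class_sep Per-informative-dimension mean separation in sd units,
#'   default 3.
#' @param pos_fraction Positive-class fraction in (0,1), default 0.35
#'   (imbalanced, as is typical of essentiality labels and the clinical
#'   benchmark tables this emulates).
#' @param n_redundant Redundant (correlated-copy) dimensions, default 0.
#' @param rho Target |Pearson r| between a redundant copy and its source,
#'   default 0.9.
#' @param seed Integer seed.
#' @return Object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_samples = 200L, n_features = 10L, n_informative = 5L,
                       class_sep = 3, pos_fraction = 0.35, n_redundant = 0L,
                       rho = 0.9, seed = 1L) {
  stopifnot(n_samples >= 4, n_features >= 1, n_informative >= 1,
            class_sep >= 0, n_redundant >= 0, rho >= 0, rho <= 1)
  if (pos_fraction <= 0 || pos_fraction >= 1) {
    stop("'pos_fraction' must lie strictly between 0 and 1", call. = FALSE)
  }
  if (n_informative + n_redundant > n_features) {
    stop("n_informative + n_redundant must not exceed n_features", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 class_sep = class_sep, pos_fraction = pos_fraction,
                 n_redundant = as.integer(n_redundant), rho = rho,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic two-class Gaussian data set
#'
#' Draws two Gaussian clusters: each informative dimension is standard
#' normal for the negative class and mean-shifted by `class_sep` for the
#' positive class; noise dimensions are standard normal for both classes;
#' each redundant dimension is `rho * z + sqrt(1 - rho^2) * eps` where `z`
#' is a standardised informative source column, giving an expected Pearson
#' correlation of `rho` with its source.  Class labels follow
#' `pos_fraction` exactly (up to rounding) and rows are shuffled; the
#' output is fully deterministic given `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return A fully labelled [labelled_set()] (provenance `"initial"`),
#'   features named `inf_*`, `red_*`, `noise_*`, sample IDs `s1..sn`.
#' @export
make_binary_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    n_pos <- max(2L, min(n - 2L, round(n * spec$pos_fraction)))
    y <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    p_inf <- spec$n_informative
    p_red <- spec$n_redundant
    p_noise <- spec$n_features - p_inf - p_red

    x_inf <- matrix(stats::rnorm(n * p_inf), n, p_inf) +
      outer(as.numeric(y), rep(spec$class_sep, p_inf))
    cols <- list(x_inf)
    nms <- paste0("inf_", seq_len(p_inf))
    if (p_red > 0L) {
      x_red <- matrix(0, n, p_red)
      for (j in seq_len(p_red)) {
        src <- x_inf[, ((j - 1L) %% p_inf) + 1L]
        z <- (src - mean(src)) / stats::sd(src)
        x_red[, j] <- spec$rho * z + sqrt(1 - spec$rho^2) * stats::rnorm(n)
      }
      cols <- c(cols, list(x_red))
      nms <- c(nms, paste0("red_", seq_len(p_red)))
    }
    if (p_noise > 0L) {
      cols <- c(cols, list(matrix(stats::rnorm(n * p_noise), n, p_noise)))
      nms <- c(nms, paste0("noise_", seq_len(p_noise)))
    }
    x <- do.call(cbind, cols)
    dimnames(x) <- list(paste0("s", seq_len(n)), nms)
    labelled_set(x, y, "initial")
  })
}

#' Generate a gene-set / p-value / network fixture
#'
#' Builds a gene-set collection with controlled pairwise overlap, log-uniform
#' p-values in `[1e-10, 1]`, and a random association network in which one
#' gene's neighbourhood coincides exactly with the first set's members
#' (planted enrichment), so that redundancy filtering, independent-set
#' selection and enrichment features can all be tested without external
#' downloads.
#'
#' Overlap profiles: `"mixed"` engineers one redundant pair (Jaccard > 0.3)
#' and keeps the remaining sets at low overlap; `"clique3"` makes the first
#' three sets pairwise redundant (a triangle in the redundancy graph);
#' `"disjoint"` makes all sets disjoint.
#'
#' @param n_sets Number of gene sets (>= 3), default 6.
#' @param universe_size Genes in the universe, default 60.
#' @param overlap_profile `"mixed"`, `"clique3"` or `"disjoint"`.
#' @param seed Integer seed.
#' @return `list(sets = <list of [gene_set()]>, pvalues = <data.frame
#'   set_id/p>, edges = <data.frame a/b>, network =
#'   <[association_network()]>, planted = list(gene, set_id), universe)`.
#' @export
make_geneset_fixture <- function(n_sets = 6L, universe_size = 60L,
                                 overlap_profile = c("mixed", "clique3", "disjoint"),
                                 seed = 1L) {
  overlap_profile <- match.arg(overlap_profile)
  stopifnot(n_sets >= 3L, universe_size >= 10L * 2L)
  with_seed(seed, {
    universe <- sprintf("g%03d", seq_len(universe_size))
    set_size <- max(4L, universe_size %/% (n_sets + 2L))

    base_of <- function() sample(universe, set_size)
    members <- vector("list", n_sets)
    if (overlap_profile == "disjoint") {
      pools <- split(universe, rep_len(seq_len(n_sets), universe_size))
      for (i in seq_len(n_sets)) {
        members[[i]] <- pools[[i]][seq_len(min(set_size, length(pools[[i]])))]
      }
    } else {
      members[[1]] <- base_of()
      n_red <- if (overlap_profile == "clique3") 3L else 2L
      for (i in seq(2L, n_red)) {
        # high-overlap variant of set 1: swap one member -> J = (k-1)/(k+1) > 0.3
        drop_g <- sample(members[[1]], 1L)
        add_g <- sample(setdiff(universe, members[[1]]), 1L)
        members[[i]] <- c(setdiff(members[[1]], drop_g), add_g)
      }
      for (i in seq(n_red + 1L, n_sets)) {
        # low-overlap sets: at most 1 shared gene with every earlier set
        repeat {
          cand <- base_of()
          max_j <- max(vapply(members[seq_len(i - 1L)],
                              function(m) jaccard(m, cand), numeric(1)))
          if (max_j <= 0.3) { members[[i]] <- cand; break }
        }
      }
    }

    p <- 10^stats::runif(n_sets, -10, 0)
    ids <- sprintf("SET%02d", seq_len(n_sets))
    sets <- mapply(function(id, m, pv) gene_set(id, m, pv),
                   ids, members, p, SIMPLIFY = FALSE)
    names(sets) <- ids

    # random background network plus a planted gene adjacent to exactly set 1
    planted_gene <- "g_planted"
    all_genes <- c(universe, planted_gene)
    n_bg <- universe_size * 2L
    bg <- unique(data.frame(
      a = sample(universe, n_bg, replace = TRUE),
      b = sample(universe, n_bg, replace = TRUE),
      stringsAsFactors = FALSE
    ))
    bg <- bg[bg$a != bg$b, ]
    edges <- rbind(bg, data.frame(a = planted_gene, b = members[[1]],
                                  stringsAsFactors = FALSE))
    network <- association_network(edges)

    list(sets = sets,
         pvalues = data.frame(set_id = ids, p = p, stringsAsFactors = FALSE),
         edges = edges,
         network = network,
         planted = list(gene = planted_gene, set_id = ids[1]),
         universe = all_genes)
  })
}

#' Write a complete synthetic fixture directory
#'
#' Emits `data.csv` (partially labelled tabular data, 20% labelled),
#' `sets.gmt`, `pvalues.csv` and `edges.tsv` in the dialects the package
#' readers consume, so end-to-end runs can start from files.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [synth_spec()] for the tabular part.
#' @param seed Seed for the gene-set fixture and the labelled/pool split.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(dir, spec = synth_spec(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- make_binary_dataset(spec)
  sp <- split_labelled_pool(ds, 0.2, seed)
  write_dataset(sp$labelled, file.path(dir, "data.csv"), pool = sp$pool)
  fx <- make_geneset_fixture(seed = seed)
  write_gmt(fx$sets, file.path(dir, "sets.gmt"))
  utils::write.csv(fx$pvalues, file.path(dir, "pvalues.csv"), row.names = FALSE)
  utils::write.table(fx$edges, file.path(dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}
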