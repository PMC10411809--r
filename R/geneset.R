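#' Construct a weighted gene set
#'
#' A gene set carries its member genes, a significance p-value and the
#' derived optimisation weight `w = 1 - log10(p) / 100`, which is >= 1 for
#' any p in (0, 1].
#'
#' @param set_id Unique set identifier.
#' @param genes Non-empty character vector of member gene IDs.
#' @param p_value Significance in (0, 1]; default 1 (weight 1).
#' @param description Free-text description (GMT column 2).
#' @return Object of class `"gene_set"`.
#' @export
gene_set <- function(set_id, genes, p_value = 1, description = "") {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene set '", set_id, "' has no members", call. = FALSE)
  structure(list(set_id = as.character(set_id), genes = genes,
                 p_value = p_value, weight = weight_from_pvalue(p_value),
                 description = description),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes, p = %.3g, weight = %.4f\n",
              x$set_id, length(x$genes), x$p_value, x$weight))
  invisible(x)
}

#' Jaccard similarity of two gene sets
#'
#' `J(A, B) = |A intersect B| / |A union B|`.
#'
#' @param a,b Character vectors of gene IDs (or [gene_set()] objects); not
#'   both empty.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (inherits(a, "gene_set")) a <- a$genes
  if (inherits(b, "gene_set")) b <- b$genes
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) {
    stop("Jaccard similarity is undefined for two empty sets", call. = FALSE)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Optimisation weight of a gene set from its p-value
#'
#' `w = 1 - log10(p) / 100`; strictly decreasing in p, equal to 1 at p = 1
#' and to 2 at p = 1e-100.
#'
#' @param p P-value in (0, 1].
#' @return The weight.
#' @export
weight_from_pvalue <- function(p) {
  if (!is.numeric(p) || any(p <= 0) || any(p > 1)) {
    stop("p-value must lie in (0, 1]", call. = FALSE)
  }
  1 - log10(p) / 100
}

#' Build the gene-set redundancy graph
#'
#' Vertices are the gene sets; an undirected edge joins every pair whose
#' Jaccard similarity strictly exceeds `tau` (redundant pairs).  The graph
#' is the input of the maximum-weight independent-set selection
#' ([select_nonredundant()]).
#'
#' @param sets List of [gene_set()] objects with distinct IDs.
#' @param tau Jaccard redundancy threshold, default 0.3 (edges require
#'   `J > tau`, strictly).
#' @return Object of class `"geneset_graph"`: `list(sets, edges =
#'   <2-column matrix of set-ID pairs>, jaccard = <named pair similarities>,
#'   tau)`.
#' @export
build_redundancy_graph <- function(sets, tau = 0.3) {
  if (!length(sets)) stop("need at least one gene set", call. = FALSE)
  ids <- vapply(sets, function(s) s$set_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate set IDs: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  names(sets) <- ids
  n <- length(sets)
  edges <- list(); jac <- numeric()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        J <- jaccard(sets[[i]], sets[[j]])
        if (J > tau) {
          edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
          jac[paste(ids[i], ids[j], sep = "|")] <- J
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(), 0, 2)
  colnames(edges) <- c("a", "b")
  structure(list(sets = sets, edges = edges, jaccard = jac, tau = tau),
            class = "geneset_graph")
}

#' @export
print.geneset_graph <- function(x, ...) {
  cat(sprintf("<geneset_graph> %d sets, %d redundant pairs (J > %.2f)\n",
              length(x$sets), nrow(x$edges), x$tau))
  invisible(x)
}

#' Select a maximum-weight non-redundant collection of gene sets
#'
#' Solves the binary optimisation: maximise the total weight
#' `sum(w_i * X_i)` subject to `X_i + X_j <= 1` for every redundancy edge
#' `{i, j}` and `X_i` in `{0, 1}` — i.e. a maximum-weight independent set of
#' the redundancy graph, keeping at most one gene set of every redundant
#' pair.  Solved exactly by branch-and-bound with a remaining-weight upper
#' bound (no approximation); practical well beyond typical collection
#' sizes.
#'
#' @param graph A [build_redundancy_graph()] result with weights on every
#'   vertex.
#' @return `list(kept = <character vector of retained set IDs, input
#'   order>, total_weight = <maximal total weight>)`.
#' @export
select_nonredundant <- function(graph) {
  ids <- names(graph$sets)
  w <- vapply(graph$sets, function(s) s$weight, numeric(1))
  adj <- mwis_adjacency(ids, graph$edges)
  sol <- mwis_branch_bound(adj, unname(w))
  list(kept = ids[sort(sol$set)], total_weight = sol$weight)
}

mwis_adjacency <- function(ids, edges) {
  adj <- rep(list(integer()), length(ids))
  if (nrow(edges)) {
    ia <- match(edges[, 1], ids)
    ib <- match(edges[, 2], ids)
    for (k in seq_along(ia)) {
      adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
      adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
    }
  }
  adj
}

# exact maximum-weight independent set: branch on the highest-degree
# remaining vertex (include / exclude), pruning when the current weight plus
# all remaining candidate weight cannot beat the incumbent
mwis_branch_bound <- function(adj, w) {
  n <- length(w)
  best_w <- -Inf
  best_set <- integer()
  rec <- function(cand, cur_set, cur_w) {
    if (cur_w + sum(w[cand]) <= best_w) return(invisible())
    idx <- which(cand)
    if (!length(idx)) {
      if (cur_w > best_w) { best_w <<- cur_w; best_set <<- cur_set }
      return(invisible())
    }
    deg <- vapply(idx, function(i) sum(cand[adj[[i]]]), numeric(1))
    if (all(deg == 0)) {                     # remaining graph edgeless: take all
      tot <- cur_w + sum(w[idx])
      if (tot > best_w) { best_w <<- tot; best_set <<- c(cur_set, idx) }
      return(invisible())
    }
    v <- idx[which.max(deg)]
    inc <- cand; inc[v] <- FALSE; inc[adj[[v]]] <- FALSE
    rec(inc, c(cur_set, v), cur_w + w[v])    # include v
    exc <- cand; exc[v] <- FALSE
    rec(exc, cur_set, cur_w)                 # exclude v
    invisible()
  }
  rec(rep(TRUE, n), integer(), 0)
  list(set = best_set, weight = best_w)
}

#' Construct a protein-association network
#'
#' Undirected adjacency built from an edge data frame; self-loops are
#' dropped and the adjacency is kept symmetric.
#'
#' @param edges Data frame (or 2-column matrix) whose first two columns are
#'   gene-ID pairs; extra columns (e.g. a confidence score) are ignored.
#' @return Object of class `"association_network"` (named list: gene ID ->
#'   character vector of neighbours).
#' @export
association_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  genes <- sort(unique(c(a, b)))
  adj <- lapply(stats::setNames(genes, genes), function(g) {
    sort(unique(c(b[a == g], a[b == g])))
  })
  structure(adj, class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  n_edges <- sum(lengths(x)) / 2
  cat(sprintf("<association_network> %d genes, %d edges\n", length(x), n_edges))
  invisible(x)
}

#' Neighbourhood gene list of a gene
#'
#' The gene list used for enrichment features: the set of all genes adjacent
#' to `gene` in the protein-association network.  Genes absent from the
#' network (or isolated) yield the empty set.
#'
#' @param network An [association_network()].
#' @param gene Gene ID.
#' @return Character vector of neighbour gene IDs (possibly empty).
#' @export
neighbour_gene_list <- function(network, gene) {
  if (!gene %in% names(network)) return(character())
  network[[gene]]
}

#' Fisher's exact over-representation feature
#'
#' One-sided (over-representation) Fisher's exact test of the 2x2 table
#' counting genes in/out of `gene_list` crossed with in/out of
#' `gene_set$genes` over the `universe`; the feature value is `-log10(p)`.
#' An empty gene list cannot be enriched and returns 0 (p = 1) by
#' convention.
#'
#' @param gene_list Character vector (e.g. a network neighbourhood).
#' @param gene_set A [gene_set()] (or plain character vector of members).
#' @param universe Non-empty character vector containing both sets.
#' @return `-log10(p)` of the one-sided test.
#' @export
fisher_enrichment_feature <- function(gene_list, gene_set, universe) {
  if (inherits(gene_set, "gene_set")) gene_set <- gene_set$genes
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty", call. = FALSE)
  gene_list <- intersect(unique(as.character(gene_list)), universe)
  gene_set <- intersect(unique(as.character(gene_set)), universe)
  if (!length(gene_list)) return(0)
  a <- length(intersect(gene_list, gene_set))
  b <- length(gene_list) - a
  c_ <- length(gene_set) - a
  d <- length(universe) - a - b - c_
  p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE),
                          alternative = "greater")$p.value
  -log10(p)
}

#' Gene-set enrichment feature matrix
#'
#' One row per query gene, one column per (kept) gene set; each entry is the
#' Fisher over-representation feature of the gene's network neighbourhood
#' against the set.  Genes without network neighbours get all-zero rows.
#'
#' @param genes Character vector of query gene IDs.
#' @param network An [association_network()].
#' @param sets List of [gene_set()] objects (typically the
#'   [select_nonredundant()] survivors).
#' @param universe Gene universe; defaults to the union of network genes and
#'   all set members.
#' @return A [feature_table()] of dimension `length(genes)` x
#'   `length(sets)`.
#' @export
geneset_feature_matrix <- function(genes, network, sets, universe = NULL) {
  if (is.null(universe)) {
    universe <- union(names(network),
                      unique(unlist(lapply(sets, function(s) s$genes))))
  }
  ids <- vapply(sets, function(s) s$set_id, character(1))
  m <- matrix(0, length(genes), length(sets),
              dimnames = list(genes, ids))
  for (g in seq_along(genes)) {
    nb <- neighbour_gene_list(network, genes[g])
    if (!length(nb)) next
    for (s in seq_along(sets)) {
      m[g, s] <- fisher_enrichment_feature(nb, sets[[s]], universe)
    }
  }
  feature_table(m)
}
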