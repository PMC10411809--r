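#' Construct a feature table
#'
#' A feature table is the universal data carrier of the package: a numeric
#' matrix of samples (rows) by features (columns) with unique sample IDs as
#' row names and unique feature names as column names.  All values must be
#' finite; missing-value handling happens at ingestion (see
#' [load_dataset()]).
#'
#' @param values Numeric matrix (or object coercible to one), samples in
#'   rows.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to existing row names, else `"1"`, `"2"`, ...
#' @param feature_names Character vector of unique feature names; defaults to
#'   existing column names, else `"f1"`, `"f2"`, ...
#' @return A numeric matrix of class `"feature_table"` with `dimnames` set.
#' @examples
#' ft <- feature_table(matrix(rnorm(6), 3, 2))
#' dim(ft)
#' @export
feature_table <- function(values, sample_ids = NULL, feature_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("feature table values must be numeric", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(values)))
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  }
  sample_ids <- as.character(sample_ids)
  feature_names <- as.character(feature_names)
  if (length(sample_ids) != nrow(values)) {
    stop("length of 'sample_ids' must equal the number of rows", call. = FALSE)
  }
  if (length(feature_names) != ncol(values)) {
    stop("length of 'feature_names' must equal the number of columns", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at sample '%s', feature '%s'",
                 sample_ids[bad[1]], feature_names[bad[2]]), call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, feature_names)
  class(values) <- c("feature_table", class(values))
  values
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features\n", nrow(x), ncol(x)))
  invisible(x)
}

as_feature_table <- function(x) {
  if (inherits(x, "feature_table")) x else feature_table(x)
}

# subset rows/columns preserving the class
ft_subset <- function(x, i = NULL, j = NULL) {
  m <- unclass(x)
  if (!is.null(i)) m <- m[i, , drop = FALSE]
  if (!is.null(j)) m <- m[, j, drop = FALSE]
  feature_table(m)
}

#' Construct a labelled set
#'
#' The labelled training data of the active learner: a [feature_table()]
#' together with per-sample binary labels and a provenance tag recording how
#' each label was obtained (`initial` seed label, `pseudo` self-assigned by
#' the heuristic, `oracle` assigned by the simulated expert, or `synthetic`
#' for SMOTE-generated rows).
#'
#' @param table A [feature_table()] (or matrix coercible to one).
#' @param labels Integer/numeric vector of 0/1 labels, one per row of
#'   `table`.
#' @param provenance Character vector (or single value, recycled) in
#'   `c("initial", "pseudo", "oracle", "synthetic")`.
#' @return An object of class `"labelled_set"` with components `table`,
#'   `labels` (named integer vector) and `provenance` (named character
#'   vector).
#' @export
labelled_set <- function(table, labels, provenance = "initial") {
  table <- as_feature_table(table)
  labels <- as.integer(labels)
  if (length(labels) != nrow(table)) {
    stop("labels must align 1:1 with table rows", call. = FALSE)
  }
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1 with no missing values", call. = FALSE)
  }
  provenance <- as.character(provenance)
  if (length(provenance) == 1L) provenance <- rep(provenance, nrow(table))
  if (length(provenance) != nrow(table)) {
    stop("provenance must have one tag per sample", call. = FALSE)
  }
  ok <- provenance %in% c("initial", "pseudo", "oracle", "synthetic")
  if (!all(ok)) {
    stop("unknown provenance tag: ", paste(unique(provenance[!ok]), collapse = ", "),
         call. = FALSE)
  }
  names(labels) <- rownames(table)
  names(provenance) <- rownames(table)
  structure(list(table = table, labels = labels, provenance = provenance),
            class = "labelled_set")
}

#' @export
print.labelled_set <- function(x, ...) {
  cat(sprintf("<labelled_set> %d samples (%d positive / %d negative), %d features\n",
              nrow(x$table), sum(x$labels == 1L), sum(x$labels == 0L), ncol(x$table)))
  tab <- table(x$provenance)
  cat("  provenance:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(x) {
  if (inherits(x, "labelled_set") || inherits(x, "pool")) nrow(x$table) else nrow(x)
}

# check both classes present (required before classifier training)
assert_two_classes <- function(labelled) {
  if (length(unique(labelled$labels)) < 2L) {
    stop("labelled set must contain both classes", call. = FALSE)
  }
  invisible(labelled)
}

#' Construct an unlabelled candidate pool
#'
#' @param table A [feature_table()] of unlabelled samples.
#' @return An object of class `"pool"`.
#' @export
pool <- function(table) {
  table <- as_feature_table(table)
  structure(list(table = table), class = "pool")
}

#' @export
print.pool <- function(x, ...) {
  cat(sprintf("<pool> %d unlabelled samples, %d features\n",
              nrow(x$table), ncol(x$table)))
  invisible(x)
}

# append a selected batch (ids/labels/provenance) from a pool to a labelled set,
# returning list(labelled, pool); the batch leaves the pool exactly once
transfer_batch <- function(labelled, pl, ids, labels, provenance) {
  stopifnot(all(ids %in% rownames(pl$table)))
  if (any(ids %in% rownames(labelled$table))) {
    stop("batch IDs overlap the labelled set; samples may be labelled only once",
         call. = FALSE)
  }
  new_tab <- rbind(unclass(labelled$table), unclass(pl$table)[ids, , drop = FALSE])
  new_lab <- labelled_set(new_tab,
                          c(labelled$labels, stats::setNames(labels, ids)),
                          c(labelled$provenance, stats::setNames(rep(provenance, length(ids)), ids)))
  keep <- setdiff(rownames(pl$table), ids)
  new_pool <- pool(unclass(pl$table)[keep, , drop = FALSE])
  list(labelled = new_lab, pool = new_pool)
}
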