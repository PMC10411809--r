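#' Load a partially labelled CSV data set
#'
#' Reads a comma-separated file with a header row, splits rows into a
#' [labelled_set()] (rows whose label cell is non-empty) and a [pool()]
#' (rows with an empty/missing label), and maps arbitrary label encodings to
#' binary 0/1 via `positive_label`.
#'
#' @param path Path to a CSV file (header row, UTF-8).
#' @param label_column Name of the label column.  It must be present; a
#'   missing column is a configuration error.  An all-empty label column is
#'   an error too (at least one labelled row is required).
#' @param positive_label Value mapped to class 1; every other non-empty label
#'   value maps to class 0.  Default `1`.
#' @param id_column Optional name of a sample-ID column; when `NULL`, row
#'   indices are used as IDs.
#' @param missing Policy for missing feature values: `"error"` (default)
#'   rejects the file naming the offending row/column; `"mean_impute"`
#'   replaces them by the column mean over observed values.
#' @return `list(labelled = <labelled_set>, pool = <pool>)`; the pool has
#'   zero rows when every row is labelled.
#' @seealso [write_dataset()] for the inverse, [split_labelled_pool()] for
#'   simulating a partially labelled set from a fully labelled one.
#' @export
load_dataset <- function(path, label_column, positive_label = 1,
                         id_column = NULL, missing = c("error", "mean_impute")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!label_column %in% names(df)) {
    stop(sprintf("label column '%s' not found in %s", label_column, path),
         call. = FALSE)
  }
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) {
      stop(sprintf("id column '%s' not found in %s", id_column, path),
           call. = FALSE)
    }
    ids <- as.character(df[[id_column]])
  } else {
    ids <- as.character(seq_len(nrow(df)))
  }
  raw_labels <- trimws(df[[label_column]])
  labelled_rows <- !is.na(raw_labels) & raw_labels != ""
  if (!any(labelled_rows)) {
    stop("no labelled rows: every value in the label column is empty",
         call. = FALSE)
  }
  feat_cols <- setdiff(names(df), c(label_column, id_column))
  if (!length(feat_cols)) stop("no feature columns in ", path, call. = FALSE)
  vals <- matrix(NA_real_, nrow(df), length(feat_cols),
                 dimnames = list(ids, feat_cols))
  for (j in seq_along(feat_cols)) {
    cell <- trimws(df[[feat_cols[j]]])
    cell[cell == ""] <- NA
    v <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(v) & !is.na(cell))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   cell[bad[1]], bad[1], feat_cols[j]), call. = FALSE)
    }
    vals[, j] <- v
  }
  if (anyNA(vals)) {
    if (missing == "error") {
      bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop(sprintf("missing feature value at row %d, column '%s' (use missing = \"mean_impute\" to impute)",
                   bad[1], feat_cols[bad[2]]), call. = FALSE)
    }
    for (j in seq_len(ncol(vals))) {
      nas <- is.na(vals[, j])
      if (any(nas)) {
        if (all(nas)) stop(sprintf("column '%s' has no observed values", feat_cols[j]),
                           call. = FALSE)
        vals[nas, j] <- mean(vals[!nas, j])
      }
    }
  }
  y <- as.integer(raw_labels[labelled_rows] == as.character(positive_label))
  lab <- labelled_set(vals[labelled_rows, , drop = FALSE], y, "initial")
  pl <- pool(vals[!labelled_rows, , drop = FALSE])
  list(labelled = lab, pool = pl)
}

#' Write a labelled set and pool back to a single CSV file
#'
#' Inverse of [load_dataset()]: labelled rows carry their 0/1 label, pool
#' rows an empty label cell.
#'
#' @param labelled A [labelled_set()].
#' @param path Output file path.
#' @param pool Optional [pool()] appended with empty labels.
#' @param label_column,id_column Column names used in the output.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(labelled, path, pool = NULL,
                          label_column = "label", id_column = "id") {
  x <- unclass(labelled$table)
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[[label_column]] <- as.character(labelled$labels)
  if (!is.null(pool) && nrow(pool$table)) {
    px <- unclass(pool$table)
    pdf <- data.frame(id = rownames(px), px, check.names = FALSE,
                      stringsAsFactors = FALSE)
    pdf[[label_column]] <- ""
    df <- rbind(df, pdf)
  }
  names(df)[1] <- id_column
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a fully labelled data set into a seed labelled set and a pool
#'
#' The benchmark protocol: a stratified-by-class random fraction of the data
#' keeps its labels (the seed set); the remainder becomes the unlabelled
#' pool, with its ground-truth labels returned separately for the simulated
#' oracle and for evaluation.
#'
#' @param dataset A fully labelled [labelled_set()].
#' @param labelled_fraction Fraction in (0,1) kept as the labelled seed set;
#'   the benchmark default is 0.2.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return `list(labelled, pool, truth)` where `truth` is a named 0/1 vector
#'   over the pool sample IDs.
#' @export
split_labelled_pool <- function(dataset, labelled_fraction = 0.2, seed = 1L) {
  if (!is.numeric(labelled_fraction) || labelled_fraction <= 0 || labelled_fraction >= 1) {
    stop("'labelled_fraction' must lie strictly between 0 and 1", call. = FALSE)
  }
  assert_two_classes(dataset)
  ids <- rownames(dataset$table)
  keep <- with_seed(seed, {
    unlist(lapply(split(ids, dataset$labels), function(cls_ids) {
      n_keep <- round(length(cls_ids) * labelled_fraction)
      sample(cls_ids, n_keep)
    }), use.names = FALSE)
  })
  if (length(unique(dataset$labels[keep])) < 2L) {
    stop("a class is absent from the labelled part; increase 'labelled_fraction'",
         call. = FALSE)
  }
  rest <- setdiff(ids, keep)
  list(
    labelled = labelled_set(ft_subset(dataset$table, keep),
                            dataset$labels[keep], "initial"),
    pool = pool(ft_subset(dataset$table, rest)),
    truth = dataset$labels[rest]
  )
}

#' Read a GMT gene-set collection
#'
#' Tab-separated GMT dialect: one set per line as
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`.  P-values are supplied
#' separately (see [read_pvalues()]) and attached with [gene_set()].
#'
#' @param path Path to a GMT file.
#' @param pvalues Optional named numeric vector (or 2-column data frame of
#'   `set_id, p`) of per-set p-values; sets without a p-value get `p = 1`.
#' @return List of [gene_set()] objects, named by set ID.
#' @export
read_gmt <- function(path, pvalues = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (is.data.frame(pvalues)) {
    pvalues <- stats::setNames(as.numeric(pvalues[[2]]), as.character(pvalues[[1]]))
  }
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("malformed GMT line (need set_id, description, >=1 member): ", ln,
           call. = FALSE)
    }
    id <- parts[1]
    p <- if (!is.null(pvalues) && id %in% names(pvalues)) unname(pvalues[id]) else 1
    gene_set(id, unique(parts[-(1:2)]), p_value = p, description = parts[2])
  })
  ids <- vapply(sets, function(s) s$set_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate set IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(sets, ids)
}

#' Write gene sets to a GMT file
#'
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$set_id, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-set p-value table
#'
#' Two-column CSV `set_id, p`.
#'
#' @param path Path to the CSV file.
#' @return Named numeric vector of p-values.
#' @export
read_pvalues <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("p-value table needs two columns (set_id, p)", call. = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read a protein-association edge list
#'
#' Whitespace- or tab-separated file with two gene-ID columns and an
#' optional third score column (ignored).  The network is undirected;
#' self-loops are dropped.
#'
#' @param path Path to the edge-list file.
#' @return An [association_network()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("a", "b", "score")[1:min(3, max(count.fields(path)))],
                          fill = TRUE)
  if (ncol(df) < 2L) stop("edge list needs at least two columns", call. = FALSE)
  association_network(data.frame(a = as.character(df[[1]]),
                                 b = as.character(df[[2]]),
                                 stringsAsFactors = FALSE))
}
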