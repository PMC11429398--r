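#' Construct a feature view
#'
#' A feature view is one samples-by-features matrix of real-valued feature
#' activations (for example deep features extracted from a convolutional
#' network's penultimate layer) together with unique feature identifiers.
#'
#' @param values Numeric matrix, `n_samples x n_features`. All entries must be
#'   finite; at least two samples and one feature are required.
#' @param feature_ids Character vector of unique feature names, one per
#'   column. Defaults to the matrix column names, or `f1, f2, ...` when
#'   absent.
#' @return An object of class `feature_view` with elements `values` and
#'   `feature_ids`.
#' @export
#' @examples
#' fv <- feature_view(matrix(rnorm(20), 5, 4))
#' dim(fv$values)
feature_view <- function(values, feature_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L)
    hawkfs_abort("a feature view needs at least 2 samples", "hawkfs_error_too_few_samples")
  if (ncol(values) < 1L)
    hawkfs_abort("a feature view needs at least 1 feature", "hawkfs_error_no_features")
  if (!all(is.finite(values)))
    hawkfs_abort("feature values must be finite (no NA/NaN/Inf)", "hawkfs_error_nonfinite")
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  }
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != ncol(values))
    hawkfs_abort("feature_ids length must equal the number of columns", "hawkfs_error_id_length")
  if (anyDuplicated(feature_ids))
    hawkfs_abort("feature ids must be unique", "hawkfs_error_duplicate_ids")
  colnames(values) <- feature_ids
  structure(list(values = values, feature_ids = feature_ids),
            class = "feature_view")
}

#' @export
print.feature_view <- function(x, ...) {
  cat(sprintf("<feature_view> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a labeled dataset
#'
#' Bundles one or two aligned feature views with a binary class label per
#' sample (0 = normal, 1 = case, e.g. OSCC). Both classes must be present.
#'
#' @param view_x A [feature_view()] (or bare numeric matrix).
#' @param labels Integer/numeric vector of 0/1 labels, one per sample.
#' @param view_y Optional second [feature_view()] aligned sample-by-sample
#'   with `view_x`.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(view_x, labels, view_y = NULL) {
  if (!inherits(view_x, "feature_view")) view_x <- feature_view(view_x)
  if (!is.null(view_y) && !inherits(view_y, "feature_view"))
    view_y <- feature_view(view_y)
  labels <- as.integer(labels)
  if (length(labels) != nrow(view_x$values))
    hawkfs_abort("labels length must equal the number of samples", "hawkfs_error_label_length")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    hawkfs_abort("labels must be binary 0/1", "hawkfs_error_labels_not_binary")
  if (length(unique(labels)) < 2L)
    hawkfs_abort("both label classes must be present", "hawkfs_error_single_class")
  if (!is.null(view_y) && nrow(view_y$values) != nrow(view_x$values))
    hawkfs_abort("view_x and view_y must have the same number of samples",
                 "hawkfs_error_sample_mismatch")
  structure(list(view_x = view_x, view_y = view_y, labels = labels),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples (%d / %d per class), view_x: %d features%s\n",
              length(x$labels), sum(x$labels == 0L), sum(x$labels == 1L),
              ncol(x$view_x$values),
              if (is.null(x$view_y)) ""
              else sprintf(", view_y: %d features", ncol(x$view_y$values))))
  invisible(x)
}

#' Number of samples in a labeled dataset
#' @param dataset A [labeled_dataset()].
#' @return Integer sample count.
#' @export
n_samples <- function(dataset) length(dataset$labels)

#' Read a delimited feature table
#'
#' Reads a comma- or tab-separated text file (delimiter auto-detected from the
#' header line) whose header row holds feature identifiers plus one label
#' column, and whose label column is coded 0/1.
#'
#' @param path Path to the delimited file.
#' @param label_column Name of the label column (default `"label"`).
#' @return A single-view [labeled_dataset()]; row order is preserved.
#' @export
read_feature_table <- function(path, label_column = "label") {
  if (!file.exists(path))
    hawkfs_abort(sprintf("file not found: %s", path), "hawkfs_error_missing_file")
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character")
  if (!label_column %in% names(df))
    hawkfs_abort(sprintf("label column '%s' not found", label_column),
                 "hawkfs_error_missing_label_column")
  if (anyDuplicated(names(df)))
    hawkfs_abort("duplicate feature ids in header", "hawkfs_error_duplicate_ids")
  labels_chr <- df[[label_column]]
  if (!all(labels_chr %in% c("0", "1")))
    hawkfs_abort("label column must be coded 0/1", "hawkfs_error_labels_not_binary")
  feat <- df[setdiff(names(df), label_column)]
  values <- suppressWarnings(vapply(feat, as.numeric, numeric(nrow(df))))
  if (anyNA(values))
    hawkfs_abort("non-numeric feature cell encountered", "hawkfs_error_nonnumeric_cell")
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(NULL, setdiff(names(df), label_column)))
  labeled_dataset(feature_view(values), as.integer(labels_chr))
}

#' Write a labeled dataset as a delimited feature table
#'
#' Writes one view of a dataset as CSV (header of feature ids plus the label
#' column), with enough digits that reading the file back reproduces the
#' values to within 1e-12.
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output file path.
#' @param view Which view to write when two are present, `"x"` or `"y"`.
#' @param label_column Name for the label column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(dataset, path, view = c("x", "y"),
                                label_column = "label") {
  view <- match.arg(view)
  if (!is.character(path) || length(path) != 1L || !nzchar(path))
    hawkfs_abort("path must be a non-empty string", "hawkfs_error_bad_path")
  fv <- if (view == "x") dataset$view_x else dataset$view_y
  if (is.null(fv))
    hawkfs_abort("requested view is absent from the dataset", "hawkfs_error_missing_view")
  if (label_column %in% fv$feature_ids)
    hawkfs_abort("label column name collides with a feature id", "hawkfs_error_duplicate_ids")
  header <- paste(c(fv$feature_ids, label_column), collapse = ",")
  body <- apply(fv$values, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  lines <- c(header, paste(body, dataset$labels, sep = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    hawkfs_abort(sprintf("cannot write to path: %s", path), "hawkfs_error_unwritable_path")
  invisible(path)
}

#' Stratified holdout split
#'
#' Splits a labeled dataset into disjoint, jointly exhaustive train and test
#' partitions. The test partition receives `round(fraction * n_c)` samples of
#' each class `c` (round half up), so both classes appear on both sides.
#' Deterministic for a fixed seed.
#'
#' @param dataset A [labeled_dataset()]; each class needs at least 2 samples.
#' @param fraction Test fraction, strictly between 0 and 1 (default 0.2, the
#'   standard holdout protocol for this problem).
#' @param seed Integer seed controlling the random assignment.
#' @return An object of class `holdout_split` with elements `train`, `test`,
#'   `fraction`, `seed`, and the row indices `test_idx`.
#' @export
holdout_split <- function(dataset, fraction = 0.2, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    hawkfs_abort("fraction must lie strictly in (0, 1)", "hawkfs_error_bad_fraction")
  labels <- dataset$labels
  if (min(table(labels)) < 2L)
    hawkfs_abort("each class needs at least 2 samples to stratify",
                 "hawkfs_error_class_too_small")
  rng <- local_rng(seed)
  test_idx <- integer(0)
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    n_test <- floor(fraction * length(idx) + 0.5)  # round half up
    n_test <- max(1L, min(length(idx) - 1L, n_test))
    test_idx <- c(test_idx, rng(sample(idx, n_test)))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(labels), test_idx)
  structure(list(train = subset_dataset(dataset, train_idx),
                 test = subset_dataset(dataset, test_idx),
                 fraction = fraction, seed = as.integer(seed),
                 test_idx = test_idx),
            class = "holdout_split")
}

#' @export
print.holdout_split <- function(x, ...) {
  cat(sprintf("<holdout_split> train n=%d, test n=%d (fraction %.3g, seed %d)\n",
              n_samples(x$train), n_samples(x$test), x$fraction, x$seed))
  invisible(x)
}

#' Subset a labeled dataset by row indices
#' @param dataset A [labeled_dataset()].
#' @param idx Integer vector of row indices.
#' @return A [labeled_dataset()] restricted to `idx`.
#' @export
subset_dataset <- function(dataset, idx) {
  vy <- if (is.null(dataset$view_y)) NULL else
    feature_view(dataset$view_y$values[idx, , drop = FALSE],
                 dataset$view_y$feature_ids)
  labeled_dataset(
    feature_view(dataset$view_x$values[idx, , drop = FALSE],
                 dataset$view_x$feature_ids),
    dataset$labels[idx], vy)
}

# Run `expr`-producing code under a private RNG stream without disturbing the
# caller's .Random.seed. Returns a function evaluating its argument under the
# stream, advancing the stream between calls.
local_rng <- function(seed) {
  state <- NULL
  local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", state, globalenv())
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr
  }
}
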