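#' Deterministic k-nearest-neighbour prediction
#'
#' Euclidean-distance KNN with fully deterministic tie handling: distance
#' ties are broken by the lower training-sample index, majority-vote ties by
#' the lower label. This keeps wrapper fitness evaluations reproducible.
#'
#' @param train_x Numeric training matrix (n_train x d).
#' @param train_y Integer 0/1 training labels.
#' @param test_x Numeric test matrix (n_test x d).
#' @param k Number of neighbours (default 5); must not exceed n_train.
#' @return Integer vector of predicted 0/1 labels.
#' @export
knn_predict <- function(train_x, train_y, test_x, k = 5L) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  n_train <- nrow(train_x)
  if (k > n_train)
    hawkfs_abort("k exceeds the training-set size", "hawkfs_error_k_too_large")
  # squared Euclidean distances via the expansion ||a-b||^2 = ||a||^2 + ||b||^2 - 2ab'
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  pred <- integer(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    nn <- order(d2[i, ], seq_len(n_train))[seq_len(k)]  # distance ties -> lower index
    votes1 <- sum(train_y[nn] == 1L)
    pred[i] <- if (votes1 * 2L > k) 1L else 0L          # vote ties -> lower label
  }
  pred
}

#' KNN holdout accuracy on a masked feature subset
#'
#' Trains the deterministic KNN on the masked columns of `train` and reports
#' the fraction of `test` samples classified correctly.
#'
#' @param train,test Single-view [labeled_dataset()] objects over the same
#'   features.
#' @param mask Logical/0-1 vector selecting feature columns; `NULL` uses all
#'   features.
#' @param k Number of neighbours (default 5).
#' @return Accuracy in [0, 1].
#' @export
knn_accuracy <- function(train, test, mask = NULL, k = 5L) {
  d <- ncol(train$view_x$values)
  if (is.null(mask)) mask <- rep(TRUE, d)
  mask <- as.logical(mask)
  if (length(mask) != d)
    hawkfs_abort("mask length must equal the feature count", "hawkfs_error_mask_length")
  if (!any(mask))
    hawkfs_abort("mask selects no features", "hawkfs_error_empty_mask")
  if (n_samples(test) < 1L)
    hawkfs_abort("empty test set", "hawkfs_error_empty_split")
  pred <- knn_predict(train$view_x$values[, mask, drop = FALSE],
                      train$labels,
                      test$view_x$values[, mask, drop = FALSE], k)
  mean(pred == test$labels)
}

#' Wrapper fitness of a feature mask
#'
#' The selection objective balancing error rate and subset size:
#' `J = sigma * (1 - accuracy) + (1 - sigma) * f_SL / f_FL`, where `f_SL` is
#' the number of selected features and `f_FL` the total. Lower is better.
#' `sigma = 0.99` puts almost all weight on accuracy with a mild pressure
#' towards small subsets.
#'
#' @param accuracy Classification accuracy in [0, 1].
#' @param n_selected Selected-feature count `f_SL`.
#' @param n_total Total feature count `f_FL`.
#' @param sigma Accuracy weight in (0, 1), default 0.99.
#' @return Fitness value in [0, 1].
#' @export
fitness_value <- function(accuracy, n_selected, n_total, sigma = 0.99) {
  if (sigma <= 0 || sigma >= 1)
    hawkfs_abort("sigma must lie strictly in (0, 1)", "hawkfs_error_bad_sigma")
  sigma * (1 - accuracy) + (1 - sigma) * (n_selected / n_total)
}

#' Evaluate the wrapper fitness of a mask with a KNN classifier
#'
#' Trains KNN on the masked columns of `train`, classifies `val`, and plugs
#' the accuracy into [fitness_value()].
#'
#' @param mask Logical/0-1 feature mask with at least one selected feature.
#' @param train,val Single-view [labeled_dataset()] objects over the same
#'   features.
#' @param sigma Accuracy weight (default 0.99).
#' @param k Number of neighbours (default 5).
#' @return Fitness value; lower is better.
#' @export
mask_fitness <- function(mask, train, val, sigma = 0.99, k = 5L) {
  mask <- as.logical(mask)
  acc <- knn_accuracy(train, val, mask, k)
  fitness_value(acc, sum(mask), length(mask), sigma)
}

#' Map a continuous position to a binary feature mask
#'
#' Each coordinate in [0, 1] is passed through a sharpened logistic transfer
#' `S(8 * (position - 0.5))`, so positions 0 and 1 select with probability
#' about 0.02 and 0.98. In `"stochastic"` mode bit j is set when a uniform
#' draw falls below the transfer value; `"deterministic"` mode thresholds the
#' transfer at 0.5. An all-zero outcome is repaired by forcing the dimension
#' with the largest transfer value to 1, so masks are never empty.
#'
#' @param position Numeric vector in [0, 1]^dim.
#' @param rands Optional uniform draws (one per dimension) for stochastic
#'   mode; defaults to `runif(length(position))` from the current RNG
#'   stream.
#' @param mode `"stochastic"` (default) or `"deterministic"`.
#' @param slope Transfer sharpness (default 8).
#' @return Integer 0/1 mask with at least one selected feature.
#' @export
binarize_position <- function(position, rands = NULL,
                              mode = c("stochastic", "deterministic"),
                              slope = 8) {
  mode <- match.arg(mode)
  transfer <- stats::plogis(slope * (position - 0.5))
  bits <- if (mode == "deterministic") {
    as.integer(transfer >= 0.5)
  } else {
    if (is.null(rands)) rands <- stats::runif(length(position))
    as.integer(rands < transfer)
  }
  if (!any(bits == 1L)) bits[which.max(transfer)] <- 1L
  bits
}
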