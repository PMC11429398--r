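#' Specification for a synthetic two-view dataset
#'
#' Describes a two-view labeled feature dataset with known ground truth,
#' emulating the situation where two deep-feature tables of different
#' dimensionality share class-informative latent structure. Informative
#' features carry a class mean shift of `effect_size` noise-standard
#' deviations plus a latent factor shared across views with loading
#' `cross_view_rho`; redundant features are random linear combinations of
#' their view's informative features plus unit noise; all remaining features
#' are pure standard Gaussian noise. Setting `rectify = TRUE` clamps negative
#' values to zero, mimicking the non-negativity of post-ReLU deep features.
#'
#' @param n_samples Number of samples (default 400).
#' @param d_x,d_y Feature counts of the two views (defaults 60 and 40,
#'   structurally analogous to the 2048/1280-dimensional deep-feature pair at
#'   a scale where tests run in seconds).
#' @param n_informative Informative features per view (default 5).
#' @param n_redundant Redundant features per view (default 0).
#' @param effect_size Class mean separation per informative feature, in units
#'   of the noise SD (default 3).
#' @param cross_view_rho Loading of the shared latent factor, in [0, 1)
#'   (default 0.5). The cross-view correlation between matched informative
#'   features is `cross_view_rho^2`.
#' @param rectify Clamp negative values to 0 (default FALSE).
#' @param class_balance Proportion of class-1 samples, in (0, 1) (default 0.5).
#' @param seed Integer seed (default 1).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 400L, d_x = 60L, d_y = 40L,
                           n_informative = 5L, n_redundant = 0L,
                           effect_size = 3, cross_view_rho = 0.5,
                           rectify = FALSE, class_balance = 0.5, seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), d_x = as.integer(d_x),
               d_y = as.integer(d_y), n_informative = as.integer(n_informative),
               n_redundant = as.integer(n_redundant),
               effect_size = effect_size, cross_view_rho = cross_view_rho,
               rectify = isTRUE(rectify), class_balance = class_balance,
               seed = as.integer(seed))
  if (spec$n_samples < 4L || spec$d_x < 1L || spec$d_y < 1L)
    hawkfs_abort("n_samples must be >= 4 and both views non-empty", "hawkfs_error_bad_spec")
  if (spec$n_informative < 1L || spec$n_redundant < 0L)
    hawkfs_abort("need n_informative >= 1 and n_redundant >= 0", "hawkfs_error_bad_spec")
  if (spec$n_informative + spec$n_redundant > min(spec$d_x, spec$d_y))
    hawkfs_abort("n_informative + n_redundant must fit in each view", "hawkfs_error_bad_spec")
  if (spec$effect_size < 0)
    hawkfs_abort("effect_size must be >= 0", "hawkfs_error_bad_spec")
  if (spec$cross_view_rho < 0 || spec$cross_view_rho >= 1)
    hawkfs_abort("cross_view_rho must lie in [0, 1)", "hawkfs_error_bad_spec")
  if (spec$class_balance <= 0 || spec$class_balance >= 1)
    hawkfs_abort("class_balance must lie strictly in (0, 1)", "hawkfs_error_bad_spec")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic two-view labeled dataset
#'
#' Draws a dataset according to a [synthetic_spec()]. Fully deterministic per
#' seed. Class-1 counts are fixed at `round(n_samples * class_balance)` and
#' label positions randomly permuted, so both classes are always present.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_dataset`: a list with the
#'   [labeled_dataset()] in `$dataset`, logical ground-truth masks
#'   `$informative_mask_x` / `$informative_mask_y` marking the planted
#'   (informative + redundant) columns of each view, and the `$spec`.
#' @export
generate_two_view <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- local_rng(spec$seed)
  n <- spec$n_samples
  m <- spec$n_informative
  r <- spec$n_redundant
  rho <- spec$cross_view_rho

  n1 <- max(2L, min(n - 2L, as.integer(floor(n * spec$class_balance + 0.5))))
  labels <- integer(n)
  labels[rng(sample.int(n, n1))] <- 1L

  g <- rng(rnorm(n))  # latent factor shared across views

  make_view <- function(d) {
    vals <- matrix(rng(rnorm(n * d)), n, d)
    cols <- rng(sample.int(d, m + r))
    inf_cols <- cols[seq_len(m)]
    red_cols <- if (r > 0L) cols[m + seq_len(r)] else integer(0)
    for (j in inf_cols) {
      vals[, j] <- labels * spec$effect_size + rho * g +
        sqrt(1 - rho^2) * rng(rnorm(n))
    }
    for (j in red_cols) {
      coefs <- rng(rnorm(m))
      vals[, j] <- vals[, inf_cols, drop = FALSE] %*% coefs + rng(rnorm(n))
    }
    mask <- rep(FALSE, d)
    mask[cols] <- TRUE
    list(values = vals, mask = mask)
  }

  vx <- make_view(spec$d_x)
  vy <- make_view(spec$d_y)
  if (spec$rectify) {
    vx$values <- pmax(vx$values, 0)
    vy$values <- pmax(vy$values, 0)
  }
  ds <- labeled_dataset(
    feature_view(vx$values, paste0("x", seq_len(spec$d_x))),
    labels,
    feature_view(vy$values, paste0("y", seq_len(spec$d_y))))
  structure(list(dataset = ds,
                 informative_mask_x = vx$mask,
                 informative_mask_y = vy$mask,
                 spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> n=%d, d_x=%d, d_y=%d, planted %d+%d per view, effect %.3g\n",
              x$spec$n_samples, x$spec$d_x, x$spec$d_y,
              x$spec$n_informative, x$spec$n_redundant, x$spec$effect_size))
  invisible(x)
}

#' Analytic class separation implied by a synthetic spec
#'
#' Closed-form Mahalanobis distance between the two class means over one
#' view's informative features, under the generator's Gaussian construction
#' (before any rectification). The informative block has mean difference
#' `effect_size` per feature and covariance
#' `(1 - rho^2) I + rho^2 J` (J the all-ones matrix), giving
#' `effect_size * sqrt(m / (1 - rho^2 + rho^2 * m))` for `m` informative
#' features. Used to calibrate tests against the empirical separation.
#'
#' @param spec A [synthetic_spec()].
#' @return The Mahalanobis distance (non-negative scalar).
#' @export
bayes_separation <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  m <- spec$n_informative
  rho <- spec$cross_view_rho
  sigma <- (1 - rho^2) * diag(m) + rho^2 * matrix(1, m, m)
  delta <- rep(spec$effect_size, m)
  sqrt(drop(crossprod(delta, solve(sigma, delta))))
}
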