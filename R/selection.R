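# Uniform draws from a deterministic substream keyed by (seed, counter),
# independent of (and not disturbing) the caller's RNG state.
substream_runif <- function(seed, counter, n) {
  mix <- (abs(as.double(seed)) * 69069 + as.double(counter) * 40503 + 1) %% 2147483647
  rng <- local_rng(as.integer(mix))
  rng(stats::runif(n))
}

#' Wrapper feature selection with binary Harris Hawks optimization
#'
#' Runs the b-IHHO (or b-HHO) wrapper: hawks move in the continuous unit
#' hypercube, each position is mapped to a feature mask by a stochastic
#' sigmoid transfer ([binarize_position()]), and masks are scored by a KNN
#' classifier through the fitness
#' `J = sigma * (1 - accuracy) + (1 - sigma) * f_SL / f_FL`
#' ([mask_fitness()]). The best mask ever evaluated is returned.
#'
#' By default the wrapper never sees the final holdout: a validation part of
#' `eval_fraction` is carved out of `train` (stratified) for fitness
#' evaluation, and `test` — when supplied — is used only for the final
#' reported accuracy, computed with KNN trained on all of `train`. Setting
#' `fitness_on_holdout = TRUE` instead evaluates fitness on `test` directly,
#' matching protocols that tune on the holdout (at the cost of optimistic
#' bias).
#'
#' @param train Single-view [labeled_dataset()] used for selection (fuse
#'   two-view data first, e.g. with [cca_fusion()] and
#'   [predict.cca_fusion()]).
#' @param test Optional single-view [labeled_dataset()] holdout over the same
#'   features, used for the reported accuracy.
#' @param variant `"ihho"` (default) or `"hho"`.
#' @param n_hawks,max_iters Population size and iteration count (defaults 20
#'   and 100).
#' @param sigma Accuracy weight of the fitness, default 0.99.
#' @param k_neighbors KNN neighbour count, default 5.
#' @param eval_fraction Fraction of `train` held out internally for fitness
#'   evaluation (default 0.2).
#' @param binarize_mode `"stochastic"` (default) or `"deterministic"`
#'   position-to-mask transfer.
#' @param fitness_on_holdout Evaluate fitness on `test` directly (requires
#'   `test`).
#' @param levy_beta Levy flight stability index (default 1.5).
#' @param seed Integer seed; the whole selection is deterministic per seed.
#' @return An object of class `feature_selection`: `mask` (integer 0/1),
#'   `selected_ids`, `n_selected`, `fitness` (best value of J),
#'   `fitness_trace` (best-so-far per iteration), `holdout_accuracy` (`NA`
#'   when no `test` given), `variant`, `sigma`, `k_neighbors`, `seed`, and
#'   the underlying `optimizer` result.
#' @export
#' @examples
#' sd <- generate_two_view(synthetic_spec(n_samples = 60, d_x = 10, d_y = 8,
#'                                        n_informative = 2, seed = 7))
#' ds <- labeled_dataset(sd$dataset$view_x, sd$dataset$labels)
#' sel <- select_features(ds, n_hawks = 6, max_iters = 5, seed = 7)
#' sel$n_selected
select_features <- function(train, test = NULL,
                            variant = c("ihho", "hho"),
                            n_hawks = 20L, max_iters = 100L,
                            sigma = 0.99, k_neighbors = 5L,
                            eval_fraction = 0.2,
                            binarize_mode = c("stochastic", "deterministic"),
                            fitness_on_holdout = FALSE,
                            levy_beta = 1.5, seed = 1L) {
  variant <- match.arg(variant)
  binarize_mode <- match.arg(binarize_mode)
  stopifnot(inherits(train, "labeled_dataset"))
  if (!is.null(train$view_y))
    hawkfs_abort("select_features expects a single (possibly fused) view; fuse first",
                 "hawkfs_error_two_views")
  d <- ncol(train$view_x$values)
  if (!is.null(test) && ncol(test$view_x$values) != d)
    hawkfs_abort("test feature count does not match train", "hawkfs_error_dim_mismatch")

  if (fitness_on_holdout) {
    if (is.null(test))
      hawkfs_abort("fitness_on_holdout requires a test set", "hawkfs_error_missing_test")
    fit_part <- train; val_part <- test
  } else {
    sp <- holdout_split(train, eval_fraction, seed = seed)
    fit_part <- sp$train; val_part <- sp$test
  }

  counter <- 0L
  best <- new.env(parent = emptyenv())
  best$J <- Inf; best$mask <- NULL
  objective <- function(position) {
    counter <<- counter + 1L
    rands <- if (binarize_mode == "stochastic")
      substream_runif(seed, counter, d) else NULL
    mask <- binarize_position(position, rands = rands, mode = binarize_mode)
    J <- mask_fitness(mask, fit_part, val_part, sigma, k_neighbors)
    if (J < best$J) { best$J <- J; best$mask <- mask }
    J
  }

  cfg <- hho_config(dim = d, n_hawks = n_hawks, max_iters = max_iters,
                    lower = 0, upper = 1, variant = variant,
                    levy_beta = levy_beta, seed = seed)
  opt <- hho_optimize(objective, cfg)

  mask <- best$mask
  acc <- if (!is.null(test))
    knn_accuracy(train, test, mask, k_neighbors) else NA_real_
  structure(list(mask = mask,
                 selected_ids = train$view_x$feature_ids[mask == 1L],
                 n_selected = sum(mask),
                 fitness = best$J,
                 fitness_trace = opt$trace,
                 holdout_accuracy = acc,
                 variant = variant, sigma = sigma,
                 k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed),
                 optimizer = opt),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> b-%s: %d of %d features, fitness %.6g%s\n",
              toupper(x$variant), x$n_selected, length(x$mask), x$fitness,
              if (is.na(x$holdout_accuracy)) ""
              else sprintf(", holdout accuracy %.4f", x$holdout_accuracy)))
  invisible(x)
}

#' @export
summary.feature_selection <- function(object, ...) {
  cat(sprintf("Wrapper feature selection (b-%s, sigma = %.3g, k = %d, seed = %d)\n",
              toupper(object$variant), object$sigma, object$k_neighbors,
              object$seed))
  cat(sprintf("  selected %d / %d features; final fitness %.6g\n",
              object$n_selected, length(object$mask), object$fitness))
  if (!is.na(object$holdout_accuracy))
    cat(sprintf("  holdout accuracy: %.4f\n", object$holdout_accuracy))
  cat(sprintf("  fitness trace: %.6g -> %.6g over %d iterations\n",
              object$fitness_trace[1], object$fitness_trace[length(object$fitness_trace)],
              length(object$fitness_trace)))
  invisible(object)
}

#' @export
plot.feature_selection <- function(x, ...) {
  plot(seq_along(x$fitness_trace), x$fitness_trace, type = "s",
       xlab = "iteration", ylab = "best-so-far fitness J",
       main = sprintf("b-%s selection", toupper(x$variant)), ...)
  invisible(x)
}
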