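#' Run a selection configuration repeatedly over consecutive seeds
#'
#' Repeats [select_features()] on identical data with seeds
#' `base_seed + 0 ... base_seed + n_runs - 1` and collects per-run holdout
#' accuracy and selected-feature count, the unit of the multi-run method
#' comparisons.
#'
#' @param train,test Single-view [labeled_dataset()] objects as in
#'   [select_features()]; `test` is required so accuracies are comparable.
#' @param n_runs Number of runs, at least 2 (default 10).
#' @param base_seed First seed (default 1).
#' @param method_name Label for reports; defaults to the variant.
#' @param ... Further arguments passed to [select_features()].
#' @return An object of class `selection_runs` with vectors `accuracies`,
#'   `n_selected`, `seeds`, the `method_name`, and the individual `fits`.
#' @export
run_selection_many <- function(train, test, n_runs = 10L, base_seed = 1L,
                               method_name = NULL, ...) {
  if (n_runs < 2L)
    hawkfs_abort("n_runs must be >= 2", "hawkfs_error_bad_config")
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  fits <- lapply(seeds, function(s)
    select_features(train, test, seed = s, ...))
  if (is.null(method_name)) method_name <- paste0("b-", toupper(fits[[1L]]$variant))
  structure(list(method_name = method_name,
                 accuracies = vapply(fits, `[[`, numeric(1), "holdout_accuracy"),
                 n_selected = vapply(fits, `[[`, integer(1), "n_selected"),
                 final_fitness = vapply(fits, `[[`, numeric(1), "fitness"),
                 seeds = seeds, fits = fits),
            class = "selection_runs")
}

#' @export
print.selection_runs <- function(x, ...) {
  cat(sprintf("<selection_runs> %s: %d runs, accuracy %.4f +/- %.4f, features %.1f +/- %.1f\n",
              x$method_name, length(x$seeds),
              mean(x$accuracies), stats::sd(x$accuracies),
              mean(x$n_selected), stats::sd(x$n_selected)))
  invisible(x)
}

#' @export
plot.selection_runs <- function(x, ..., ylab = "holdout accuracy") {
  runs <- c(list(x), Filter(function(o) inherits(o, "selection_runs"), list(...)))
  boxplot(lapply(runs, `[[`, "accuracies"),
          names = vapply(runs, `[[`, character(1), "method_name"),
          ylab = ylab)
  invisible(x)
}

#' Pooled two-sample t-test with Cohen's d
#'
#' Compares two vectors of per-run scores (e.g. accuracies of two selection
#' methods) with a two-sided Student t-test on the pooled variance
#' (`n_a + n_b - 2` degrees of freedom) and reports the standardized mean
#' difference. The sign convention is first argument minus second, so a
#' negative Cohen's d means the first method's mean is lower.
#'
#' @param a,b Numeric vectors, each of length >= 2, with nonzero pooled
#'   variance.
#' @param welch Use the Welch (unequal-variance) test instead of the pooled
#'   one; Cohen's d still uses the pooled SD.
#' @return An object of class `method_comparison`: `t_statistic`, `p_value`,
#'   `cohens_d`, `mean_diff`, `df`, `n_a`, `n_b`.
#' @export
#' @examples
#' two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
two_sample_ttest <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    hawkfs_abort("each sample needs at least 2 values", "hawkfs_error_too_few_values")
  ht <- tryCatch(stats::t.test(a, b, var.equal = !welch),
                 error = function(e)
                   hawkfs_abort("zero pooled variance: samples are constant",
                                "hawkfs_error_zero_variance"))
  structure(list(t_statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 cohens_d = cohens_d(a, b),
                 mean_diff = mean(a) - mean(b),
                 df = unname(ht$parameter),
                 n_a = length(a), n_b = length(b),
                 welch = welch),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s): t = %.4f, df = %.4g, p = %.4g\n",
              if (x$welch) "Welch" else "pooled", x$t_statistic, x$df, x$p_value))
  cat(sprintf("mean difference = %.4g, Cohen's d = %.4g (n = %d, %d)\n",
              x$mean_diff, x$cohens_d, x$n_a, x$n_b))
  invisible(x)
}

#' Cohen's d effect size (pooled SD)
#'
#' `(mean(a) - mean(b)) / s_p` with
#' `s_p = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return The standardized mean difference; antisymmetric in its arguments
#'   and invariant to common rescaling.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    hawkfs_abort("each sample needs at least 2 values", "hawkfs_error_too_few_values")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0)
    hawkfs_abort("zero pooled SD", "hawkfs_error_zero_variance")
  (mean(a) - mean(b)) / sp
}

#' Five-number box summary
#'
#' Minimum, first quartile, median, third quartile and maximum with
#' linear-interpolation quartiles (quantile type 7), the numbers behind a
#' box-whisker plot of per-run accuracies.
#'
#' @param values Numeric vector of length >= 1.
#' @return Named numeric vector `(min, q1, median, q3, max)`.
#' @export
box_summary <- function(values) {
  if (length(values) < 1L)
    hawkfs_abort("empty input", "hawkfs_error_empty_input")
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  stats::setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Compare two multi-run selection results
#'
#' Convenience wrapper applying [two_sample_ttest()] to the per-run
#' accuracies of two [run_selection_many()] results.
#'
#' @param runs_a,runs_b `selection_runs` objects.
#' @param welch Use the Welch test.
#' @return A `method_comparison`.
#' @export
compare_runs <- function(runs_a, runs_b, welch = FALSE) {
  stopifnot(inherits(runs_a, "selection_runs"), inherits(runs_b, "selection_runs"))
  two_sample_ttest(runs_a$accuracies, runs_b$accuracies, welch = welch)
}
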