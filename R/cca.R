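#' Fit a canonical correlation fusion transform between two feature views
#'
#' Canonical correlation analysis (CCA) finds paired linear projections
#' `W_x`, `W_y` of two feature views that maximize the correlation between
#' the projected coordinates. The fitted transform is the basis for feature
#' fusion: both views are projected onto their canonical coordinates and the
#' projections combined (concatenated by default) into a single fused
#' feature vector, e.g. a 2048-dimensional and a 1280-dimensional deep
#' feature view fuse into a 2560-dimensional vector in `"concat"` mode.
#'
#' The solver works on column-centered data and solves the paired
#' eigenproblem
#' `(C_xx)^-1 C_xy (C_yy)^-1 C_yx W_x = sigma W_x` (and its mirror) with
#' ridge-regularized within-view covariances, via a Cholesky-symmetrized
#' eigendecomposition on the lower-dimensional view. All
#' `k = min(d_x, d_y)` canonical pairs are retained regardless of sample
#' rank; pairs beyond the data rank carry the (near-zero) correlations the
#' regularized problem assigns them, and their loading columns are completed
#' to a basis orthonormal under the regularized covariance metric. Columns
#' are centered but not variance-scaled (CCA is scale-invariant). The sign
#' of each pair is fixed so the first non-negligible loading of each `W_x`
#' column is positive.
#'
#' @param X,Y [feature_view()] objects (or bare matrices) with the same
#'   number of samples (at least 3).
#' @param ridge Non-negative ridge added to the diagonal of each within-view
#'   covariance. Default `NULL` uses `1e-6 * mean(diag(C))` per view, which
#'   keeps the problem well-posed when samples are fewer than features.
#' @param fusion_mode `"concat"` (default) stacks the two k-dimensional
#'   projections into a 2k-dimensional fused vector; `"sum"` adds them into a
#'   k-dimensional vector.
#' @return An object of class `cca_fusion` with elements `mean_x`, `mean_y`,
#'   `W_x` (d_x x k), `W_y` (d_y x k), `correlations` (length k,
#'   non-increasing), `ridge` (the two effective ridge values used), and
#'   `fusion_mode`.
#' @seealso [predict.cca_fusion()] to transform and fuse new data,
#'   [canonical_correlations()].
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 50, 4)
#' Y <- X %*% matrix(rnorm(12), 4, 3) + 0.5 * matrix(rnorm(150), 50, 3)
#' fit <- cca_fusion(X, Y)
#' canonical_correlations(fit)
#' fused <- predict(fit, X, Y)
cca_fusion <- function(X, Y, ridge = NULL, fusion_mode = c("concat", "sum")) {
  fusion_mode <- match.arg(fusion_mode)
  Xm <- if (inherits(X, "feature_view")) X$values else as.matrix(X)
  Ym <- if (inherits(Y, "feature_view")) Y$values else as.matrix(Y)
  if (nrow(Xm) != nrow(Ym))
    hawkfs_abort("X and Y must have the same number of samples",
                 "hawkfs_error_sample_mismatch")
  n <- nrow(Xm)
  if (n < 3L)
    hawkfs_abort("CCA needs at least 3 samples", "hawkfs_error_too_few_samples")
  if (!all(is.finite(Xm)) || !all(is.finite(Ym)))
    hawkfs_abort("views must be finite", "hawkfs_error_nonfinite")
  if (!is.null(ridge) && (!is.numeric(ridge) || any(ridge < 0)))
    hawkfs_abort("ridge must be >= 0", "hawkfs_error_bad_ridge")

  mean_x <- colMeans(Xm); mean_y <- colMeans(Ym)
  Xc <- sweep(Xm, 2L, mean_x); Yc <- sweep(Ym, 2L, mean_y)
  Cxx <- crossprod(Xc) / (n - 1)
  Cyy <- crossprod(Yc) / (n - 1)
  Cxy <- crossprod(Xc, Yc) / (n - 1)

  eff_ridge <- function(C) if (is.null(ridge)) 1e-6 * mean(diag(C)) else ridge
  rx <- eff_ridge(Cxx); ry <- eff_ridge(Cyy)
  diag(Cxx) <- diag(Cxx) + rx
  diag(Cyy) <- diag(Cyy) + ry

  # Solve on the smaller view, then back out the larger view's loadings.
  swap <- ncol(Xm) < ncol(Ym)
  if (swap) {
    tmp <- Cxx; Cxx <- Cyy; Cyy <- tmp
    Cxy <- t(Cxy)
  }
  # Now ncol(Cyy) = k = min(d_x, d_y). Symmetrize U^-T Cyx Cxx^-1 Cxy U^-1
  # with U the Cholesky factor of the regularized Cyy.
  Uy <- chol(Cyy)
  B <- crossprod(Cxy, solve(Cxx, Cxy))       # Cyx Cxx^-1 Cxy, k x k
  T1 <- backsolve(Uy, B, transpose = TRUE)   # U^-T B
  M <- t(backsolve(Uy, t(T1), transpose = TRUE))
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  corr <- sqrt(pmax(eig$values, 0))
  W_small <- backsolve(Uy, eig$vectors)      # k x k, orthonormal in Cyy metric

  # Larger view: raw directions Cxx^-1 Cxy w, normalized in the Cxx metric;
  # columns with (near-)zero canonical correlation are completed to an
  # orthonormal basis of the metric's complement.
  CW <- Cxy %*% W_small
  W_big <- solve(Cxx, CW)
  norm2 <- colSums(W_big * CW)               # = w^T (Cxx + r I) w before scaling
  tol <- max(norm2, 0) * 1e-10 + 1e-300
  good <- norm2 > tol
  W_big[, good] <- sweep(W_big[, good, drop = FALSE], 2L, sqrt(norm2[good]), "/")
  if (any(!good)) {
    Ux <- chol(Cxx)
    d_big <- ncol(Cxx)
    n_bad <- sum(!good)
    Zg <- Ux %*% W_big[, good, drop = FALSE]
    E <- diag(d_big)[, seq_len(n_bad), drop = FALSE]
    E <- E - Zg %*% crossprod(Zg, E)
    E <- E - Zg %*% crossprod(Zg, E)
    Qf <- qr.Q(qr(E))[, seq_len(n_bad), drop = FALSE]
    W_big[, !good] <- backsolve(Ux, Qf)
  }

  if (swap) { W_x <- W_small; W_y <- W_big } else { W_x <- W_big; W_y <- W_small }

  # reproducible sign: first non-negligible loading of each W_x column positive
  for (j in seq_len(ncol(W_x))) {
    lead <- which(abs(W_x[, j]) > 1e-12)[1]
    if (!is.na(lead) && W_x[lead, j] < 0) {
      W_x[, j] <- -W_x[, j]; W_y[, j] <- -W_y[, j]
    }
  }

  structure(list(mean_x = mean_x, mean_y = mean_y,
                 W_x = W_x, W_y = W_y,
                 correlations = corr,
                 ridge = c(x = rx, y = ry),
                 fusion_mode = fusion_mode,
                 n = n),
            class = "cca_fusion")
}

#' Transform two views through a fitted fusion model
#'
#' Centers each view by the stored training means, projects through the
#' canonical loadings, and combines the projections: `"concat"` stacks the
#' two k-dimensional projections into a 2k-dimensional fused vector, `"sum"`
#' adds them into a k-dimensional one.
#'
#' @param object A fitted [cca_fusion()] model.
#' @param X,Y Feature views (or matrices) with the dimensions the model was
#'   fitted on.
#' @param fusion_mode Override the model's fusion mode.
#' @param ... Unused.
#' @return A [feature_view()] holding the fused coordinates.
#' @export
predict.cca_fusion <- function(object, X, Y,
                               fusion_mode = object$fusion_mode, ...) {
  Xm <- if (inherits(X, "feature_view")) X$values else as.matrix(X)
  Ym <- if (inherits(Y, "feature_view")) Y$values else as.matrix(Y)
  if (ncol(Xm) != nrow(object$W_x) || ncol(Ym) != nrow(object$W_y))
    hawkfs_abort("view dimensions do not match the fitted model",
                 "hawkfs_error_dim_mismatch")
  if (nrow(Xm) != nrow(Ym))
    hawkfs_abort("X and Y must have the same number of samples",
                 "hawkfs_error_sample_mismatch")
  Zx <- sweep(Xm, 2L, object$mean_x) %*% object$W_x
  Zy <- sweep(Ym, 2L, object$mean_y) %*% object$W_y
  k <- ncol(Zx)
  if (fusion_mode == "concat") {
    feature_view(cbind(Zx, Zy),
                 c(paste0("ccx", seq_len(k)), paste0("ccy", seq_len(k))))
  } else {
    feature_view(Zx + Zy, paste0("cc", seq_len(k)))
  }
}

#' Canonical correlations of a fitted fusion model
#' @param model A fitted [cca_fusion()] model.
#' @return Numeric vector of canonical correlations, non-increasing, each in
#'   [0, 1] up to numerical noise.
#' @export
canonical_correlations <- function(model) {
  stopifnot(inherits(model, "cca_fusion"))
  model$correlations
}

#' @export
coef.cca_fusion <- function(object, ...) {
  list(W_x = object$W_x, W_y = object$W_y)
}

#' @export
print.cca_fusion <- function(x, ...) {
  k <- length(x$correlations)
  cat(sprintf("<cca_fusion> %d x %d -> %d canonical pairs (%s fusion, dim %d)\n",
              nrow(x$W_x), nrow(x$W_y), k, x$fusion_mode,
              if (x$fusion_mode == "concat") 2L * k else k))
  cat(sprintf("leading correlations: %s\n",
              paste(sprintf("%.3f", utils::head(x$correlations, 5)), collapse = " ")))
  invisible(x)
}

#' @export
summary.cca_fusion <- function(object, ...) {
  structure(list(d_x = nrow(object$W_x), d_y = nrow(object$W_y),
                 k = length(object$correlations),
                 fused_dim = if (object$fusion_mode == "concat")
                   2L * length(object$correlations) else length(object$correlations),
                 correlations = object$correlations,
                 ridge = object$ridge, n = object$n,
                 fusion_mode = object$fusion_mode),
            class = "summary.cca_fusion")
}

#' @export
print.summary.cca_fusion <- function(x, ...) {
  cat(sprintf("Canonical correlation fusion fitted on %d samples\n", x$n))
  cat(sprintf("  views: %d and %d features; %d canonical pairs; fused dim %d (%s)\n",
              x$d_x, x$d_y, x$k, x$fused_dim, x$fusion_mode))
  cat(sprintf("  ridge: %.3g (x), %.3g (y)\n", x$ridge[["x"]], x$ridge[["y"]]))
  cat("  correlations:\n")
  print(summary(x$correlations))
  invisible(x)
}
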