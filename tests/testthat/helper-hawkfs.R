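# Shared fixture builders for the test suite.

# A small labeled dataset with d Gaussian features, balanced labels.
make_dataset <- function(n = 20, d = 3, seed = 1) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  labeled_dataset(matrix(rnorm(n * d), n, d), labels)
}

# Two well-separated point clouds (class means 0 and `sep` on every feature).
make_separable <- function(n = 40, d = 2, sep = 10, seed = 1) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), each = n / 2)
  vals <- matrix(rnorm(n * d), n, d) + sep * labels
  labeled_dataset(vals, labels)
}

# Independent SVD-based CCA oracle: whiten both views explicitly through the
# inverse square root of their (optionally ridged) covariances, then take the
# singular values / vectors of the whitened cross-covariance. Deliberately a
# different route from the fitting code.
cca_svd_oracle <- function(X, Y, ridge = 0) {
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  Cxx <- crossprod(Xc) / (n - 1) + diag(ridge, ncol(X))
  Cyy <- crossprod(Yc) / (n - 1) + diag(ridge, ncol(Y))
  Cxy <- crossprod(Xc, Yc) / (n - 1)
  inv_sqrt <- function(C) {
    e <- eigen(C, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nrow(C)) %*% t(e$vectors)
  }
  sv <- svd(inv_sqrt(Cxx) %*% Cxy %*% inv_sqrt(Cyy))
  sv$d[seq_len(min(ncol(X), ncol(Y)))]
}
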