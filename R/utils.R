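# Validate a genes-by-cells count matrix: numeric, nonnegative, integral.
check_count_matrix <- function(X) {
  if (inherits(X, "sparseMatrix")) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("`X` must be a numeric genes-by-cells matrix.", call. = FALSE)
  }
  if (nrow(X) < 1 || ncol(X) < 1) {
    stop("`X` must have at least one gene and one cell.", call. = FALSE)
  }
  if (anyNA(X) || any(X < 0) || any(X != floor(X))) {
    stop("`X` must contain only nonnegative integer counts.", call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}

# Draw n p-variate Gaussian vectors with zero mean and correlation R, via
# eigen decomposition with negative eigenvalues clipped to zero. Handles the
# rank-deficient case (more genes than training cells). Returns p x n.
rmvnorm_eigen <- function(n, R) {
  p <- nrow(R)
  if (p == 0) return(matrix(0, 0, n))
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p)
  L %*% matrix(stats::rnorm(p * n), p, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
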