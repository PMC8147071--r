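# Independent samplers and brute-force oracles used across the suite.
# These deliberately avoid the package's own quantile/CDF code paths.

# ZINB sampler via the two-stage hierarchy (Bernoulli dropout + NB draw);
# psi = Inf gives (zero-inflated) Poisson.
rzinb_oracle <- function(n, p = 0, psi = Inf, mu = 1) {
  z <- stats::rbinom(n, 1, p)
  x <- if (is.finite(psi)) {
    stats::rnbinom(n, size = psi, mu = mu)
  } else {
    stats::rpois(n, mu)
  }
  ifelse(z == 1, 0L, x)
}

# Brute-force generalised-inverse CDF: scan k = 0, 1, 2, ... accumulating
# the pmf until it reaches q.
quantile_scan_oracle <- function(q, p = 0, psi = Inf, mu = 1) {
  pmf <- function(k) {
    base <- if (is.finite(psi)) {
      stats::dnbinom(k, size = psi, mu = mu)
    } else {
      stats::dpois(k, mu)
    }
    p * (k == 0) + (1 - p) * base
  }
  k <- 0
  acc <- pmf(0)
  while (acc < q) {
    k <- k + 1
    acc <- acc + pmf(k)
    if (k > 1e6) stop("oracle scan did not terminate")
  }
  k
}

# O(n^2) pair-counting Kendall tau-b with tie correction.
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Small labelled two-type count matrix for end-to-end tests.
make_demo_matrix <- function(n_per_type = 60, seed = 11) {
  set.seed(seed)
  g <- 15
  X1 <- matrix(rpois(g * n_per_type, lambda = rep(seq(1, 8, length.out = g),
                                                  n_per_type)),
               g, n_per_type)
  X2 <- matrix(rnbinom(g * n_per_type, size = 2,
                       mu = rep(seq(2, 12, length.out = g), n_per_type)),
               g, n_per_type)
  X <- cbind(X1, X2)
  rownames(X) <- sprintf("g%02d", seq_len(g))
  colnames(X) <- sprintf("c%03d", seq_len(ncol(X)))
  list(X = X, labels = rep(c("alpha", "beta"), each = n_per_type))
}
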