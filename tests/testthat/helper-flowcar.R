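# Shared fixtures built in code.

# random symmetric weight matrix (max-scaled) on N ports, connected-ish
random_network <- function(N, seed, edge_prob = 0.6) {
  set.seed(seed)
  raw <- matrix(0, N, N)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    if (stats::runif(1) < edge_prob) {
      v <- stats::rlnorm(1, 2, 1)
      raw[i, j] <- v; raw[j, i] <- v
    }
  }
  if (max(raw) == 0) { raw[1, 2] <- raw[2, 1] <- 1 }
  rownames(raw) <- colnames(raw) <- sprintf("N%02d", seq_len(N))
  suppressWarnings(scale_weights(raw))
}

# dense-matrix oracle for the conditional of a joint N(0, Q^-1)
conditional_from_precision <- function(theta, i, Q) {
  Qm <- if (inherits(Q, "precision_matrix")) Q$Q else Q
  list(mean = -sum(Qm[i, -i] * theta[-i]) / Qm[i, i],
       variance = 1 / Qm[i, i])
}

# independent multivariate-normal log-density via eigendecomposition of
# the covariance (a different route than the package's Cholesky-of-Q)
mvn_logpdf_dense <- function(x, Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  d <- length(x)
  z <- crossprod(e$vectors, x)
  -0.5 * d * log(2 * pi) - 0.5 * sum(log(e$values)) -
    0.5 * sum(z^2 / e$values)
}

# intercept-only Gaussian toy dataset for conjugate checks
toy_gaussian <- function(n, mu = 1.3, seed = 99) {
  set.seed(seed)
  list(list(family = "gaussian", y = stats::rnorm(n, mu, 1), n = NULL,
            X = matrix(nrow = n, ncol = 0), label = "toy", sigma = 1))
}

# small but informative simulated survey scenario for quick fits
quick_scenario <- function(seed, ...) {
  scenario_config(n_ports = 30, seed = seed, ...)
}
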