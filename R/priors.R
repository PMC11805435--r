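#' Hyperprior configuration
#'
#' Defaults follow the weakly-informative choices used throughout:
#' fixed effects N(0, 1/0.001); precision tau ~ gamma(shape 1, scale
#' 100); dependence lambda ~ uniform(0, 1); the 2 x 2 cross-dataset
#' precision Lambda ~ Wishart(df 4, scale I), whose prior mean is
#' df * scale = 4 I (the scale — not rate — convention).
#'
#' @param beta_prec precision of the normal prior on intercepts and
#'   regression coefficients.
#' @param tau_shape,tau_scale gamma prior on tau (univariate models).
#' @param wishart_df,wishart_scale Wishart prior on Lambda (multivariate
#'   models).
#' @return list of class \code{hyper_priors}.
#' @export
hyper_priors <- function(beta_prec = 0.001, tau_shape = 1, tau_scale = 100,
                         wishart_df = 4, wishart_scale = diag(2)) {
  stopifnot(beta_prec > 0, tau_shape > 0, tau_scale > 0,
            wishart_df > 1, is.matrix(wishart_scale))
  structure(list(beta_prec = beta_prec, tau_shape = tau_shape,
                 tau_scale = tau_scale, tau_rate = 1 / tau_scale,
                 wishart_df = wishart_df, wishart_scale = wishart_scale),
            class = "hyper_priors")
}

#' Log-density of the Wishart distribution (scale convention)
#'
#' log d(X; df, S) with E[X] = df * S; used in the joint log-posterior.
#'
#' @param X symmetric positive-definite p x p matrix.
#' @param df degrees of freedom, > p - 1.
#' @param scale scale matrix S.
#' @return log-density (scalar).
#' @export
dwishart_log <- function(X, df, scale) {
  p <- nrow(X)
  ldX <- determinant(X, logarithm = TRUE)$modulus
  ldS <- determinant(scale, logarithm = TRUE)$modulus
  lmvgamma <- (p * (p - 1) / 4) * log(pi) +
    sum(lgamma(df / 2 + (1 - seq_len(p)) / 2))
  as.numeric(
    0.5 * (df - p - 1) * ldX - 0.5 * sum(diag(solve(scale, X))) -
      0.5 * df * p * log(2) - 0.5 * df * ldS - lmvgamma
  )
}

prior_logdensity_fixed <- function(coefs, priors) {
  sum(stats::dnorm(coefs, 0, sqrt(1 / priors$beta_prec), log = TRUE))
}
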