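dataset_loglik <- function(d, eta) {
  switch(d$family,
    binomial = survey_loglik(d$y, d$n, eta),
    poisson = presence_only_loglik(d$y, eta),
    gaussian = sum(stats::dnorm(d$y, eta,
                                if (is.null(d$sigma)) 1 else d$sigma,
                                log = TRUE)))
}

#' Joint log-posterior density (reference implementation)
#'
#' Straight-line evaluation of the hierarchical model's unnormalized
#' log-posterior: observation log-likelihoods, the GMRF log-density of
#' the latent effects (absent for a GLM), and the hyperprior
#' log-densities. Parameters outside their support (tau <= 0, lambda
#' outside [0,1), Lambda not positive definite) return -Inf. This is the
#' density the MCMC sampler targets and serves as its audit point.
#'
#' @param params list with \code{coef} (list per dataset of
#'   c(intercept, beta...)), and for latent models \code{theta} (matrix
#'   N x n_datasets), plus \code{tau} and \code{lam} (car) or
#'   \code{cross} (a \code{\link{cross_precision}}) and \code{lam}
#'   (mcar).
#' @param datasets likelihood datasets as in \code{\link{fit_model}}.
#' @param model_type \code{"glm"}, \code{"car"}, \code{"mcar_dt"} or
#'   \code{"mcar_sp"}.
#' @param network \code{port_network} (latent models only).
#' @param priors a \code{\link{hyper_priors}}.
#' @return scalar log-posterior (unnormalized).
#' @export
log_posterior <- function(params, datasets, model_type, network = NULL,
                          priors = hyper_priors()) {
  model_type <- match.arg(model_type, c("glm", "car", "mcar_dt", "mcar_sp"))
  nd <- length(datasets)
  lp <- 0
  theta_mat <- params$theta
  for (j in seq_len(nd)) {
    d <- datasets[[j]]
    co <- params$coef[[j]]
    th <- if (model_type == "glm" || is.null(theta_mat)) 0 else theta_mat[, j]
    if (length(d$y) > 0) {
      X <- cbind(1, as.matrix(d$X))
      eta <- drop(X %*% co) + th
      lp <- lp + dataset_loglik(d, eta)
    }
    lp <- lp + prior_logdensity_fixed(co, priors)
  }
  if (model_type == "glm") return(lp)

  lam <- params$lam
  if (!is.numeric(lam) || lam < 0 || lam >= 1) return(-Inf)
  if (nd == 1L) {
    tau <- params$tau
    if (!is.numeric(tau) || tau <= 0) return(-Inf)
    Q <- leroux_precision(network, lam, tau)
    lp <- lp + gmrf_logpdf(theta_mat[, 1], Q)
    lp <- lp + stats::dgamma(tau, shape = priors$tau_shape,
                             scale = priors$tau_scale, log = TRUE)
  } else {
    cross <- params$cross
    if (is.null(cross)) return(-Inf)
    ev <- eigen(cross$Lambda, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) return(-Inf)
    Q <- mcar_precision(network, lam, cross)
    lp <- lp + gmrf_logpdf(as.numeric(theta_mat), Q)
    lp <- lp + dwishart_log(cross$Lambda, priors$wishart_df,
                            priors$wishart_scale)
  }
  lp + stats::dunif(lam, 0, 1, log = TRUE)
}

#' Pointwise log-likelihood over posterior draws
#'
#' For each dataset in a fit, the draws x ports matrix of pointwise
#' observation log-likelihoods (full pmf including constants), the raw
#' material of DIC and WAIC.
#'
#' @param samples a \code{posterior_samples} object.
#' @return named list (one per dataset) of matrices, plus attribute
#'   \code{"mean_linkpar"}: the posterior mean of the likelihood-level
#'   parameter (p or lambda) per port.
#' @export
pointwise_loglik <- function(samples) {
  dm <- draw_matrix(samples)
  nd <- length(samples$datasets)
  N <- samples$N
  out <- vector("list", nd)
  names(out) <- samples$labels
  for (j in seq_len(nd)) {
    d <- samples$datasets[[j]]
    lab <- d$label
    cn <- colnames(as.matrix(d$X))
    coef_cols <- c(paste0("alpha_", lab),
                   if (length(cn)) paste0("beta_", lab, "_", cn))
    co <- dm[, coef_cols, drop = FALSE]
    X <- cbind(1, as.matrix(d$X))
    eta <- co %*% t(X)  # draws x N
    if (samples$model_type != "glm") {
      th_cols <- paste0("theta_", lab, "[", seq_len(N), "]")
      eta <- eta + dm[, th_cols, drop = FALSE]
    }
    ll <- matrix(0, nrow(eta), N)
    if (d$family == "binomial") {
      linkpar <- stats::plogis(eta)
      for (i in seq_len(N))
        ll[, i] <- stats::dbinom(d$y[i], d$n[i], linkpar[, i], log = TRUE)
    } else if (d$family == "poisson") {
      linkpar <- exp(eta)
      for (i in seq_len(N))
        ll[, i] <- stats::dpois(d$y[i], linkpar[, i], log = TRUE)
    } else {
      sg <- if (is.null(d$sigma)) 1 else d$sigma
      linkpar <- eta
      for (i in seq_len(N))
        ll[, i] <- stats::dnorm(d$y[i], eta[, i], sg, log = TRUE)
    }
    attr(ll, "mean_linkpar") <- colMeans(linkpar)
    attr(ll, "family") <- d$family
    out[[j]] <- ll
  }
  out
}
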