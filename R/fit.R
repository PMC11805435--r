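#' MCMC run configuration
#'
#' @param n_chains number of chains (default 4; at least 2 needed for
#'   split R-hat).
#' @param n_warmup adaptation iterations discarded per chain.
#' @param n_iter retained iterations per chain.
#' @param thin thinning interval.
#' @param seed integer seed (mandatory); chain seeds are derived from it
#'   so the same configuration reproduces identical draws.
#' @param rhat_threshold convergence flag threshold on split R-hat.
#' @return list of class \code{mcmc_control}.
#' @export
mcmc_control <- function(n_chains = 4, n_warmup = 2000, n_iter = 2000,
                         thin = 1, seed, rhat_threshold = 1.05) {
  if (missing(seed)) stop("mcmc_control requires an explicit seed")
  stopifnot(n_chains >= 1, n_warmup >= 0, n_iter >= thin, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_iter = as.integer(n_iter), thin = as.integer(thin),
                 seed = as.integer(seed),
                 rhat_threshold = rhat_threshold),
            class = "mcmc_control")
}

family_code <- function(family) {
  switch(family, binomial = 0L, poisson = 1L, gaussian = 2L,
         stop("unknown family: ", family))
}

validate_datasets <- function(datasets, model_type) {
  nd <- length(datasets)
  if (model_type %in% c("glm", "car") && nd != 1L)
    stop(model_type, " models take exactly one dataset")
  if (model_type %in% c("mcar_dt", "mcar_sp") && nd != 2L)
    stop("multivariate models take exactly two datasets")
  N <- length(datasets[[1]]$y)
  for (d in datasets) {
    stopifnot(length(d$y) == N)
    if (d$family == "binomial") {
      if (any(d$y < 0) || any(d$y > d$n))
        stop("binomial dataset needs 0 <= y <= n")
    } else if (d$family == "poisson") {
      if (any(d$y < 0) || any(d$y != round(d$y)))
        stop("poisson dataset needs nonnegative integer y")
    }
  }
  invisible(N)
}

param_names_for <- function(datasets, model_type, N) {
  nm <- character(0)
  for (d in datasets) {
    cn <- colnames(d$X)
    nm <- c(nm, paste0("alpha_", d$label),
            if (length(cn)) paste0("beta_", d$label, "_", cn))
  }
  if (model_type != "glm") {
    for (d in datasets)
      nm <- c(nm, paste0("theta_", d$label, "[", seq_len(N), "]"))
    nm <- c(nm, if (length(datasets) == 1L) c("tau", "lam")
            else c("tau1", "tau2", "rho", "lam"))
  }
  nm
}

#' Fit a GLM, Leroux CAR, or MCAR introduction-risk model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs sampling of the full hierarchical
#' posterior: componentwise random-walk updates for intercepts and
#' regression coefficients, single-site updates of the latent network
#' effects against their Gaussian full conditionals, exact conjugate
#' draws for tau (gamma) and Lambda (Wishart), and a logit-scale random
#' walk for lambda with the log-determinant evaluated from the
#' eigenvalues of diag(W1) - W.
#'
#' @param datasets list of likelihood datasets (see
#'   \code{\link{build_datasets}}); each has \code{family}
#'   (\code{"binomial"}, \code{"poisson"} or \code{"gaussian"}),
#'   \code{y}, \code{n} (binomial trials; ignored otherwise), \code{X}
#'   (covariate matrix without intercept), \code{label}, and optionally
#'   \code{sigma} for the Gaussian family.
#' @param model_type \code{"glm"}, \code{"car"}, \code{"mcar_dt"} or
#'   \code{"mcar_sp"}.
#' @param network \code{port_network}; required unless
#'   \code{model_type = "glm"}.
#' @param priors a \code{\link{hyper_priors}} object.
#' @param control an \code{\link{mcmc_control}} object (carries the
#'   seed).
#' @return object of class \code{posterior_samples}: per-chain draw
#'   matrices with named columns, the data and configuration needed to
#'   recompute likelihoods, and a \code{\link{run_diagnostics}} report
#'   when at least two chains were run. If any R-hat exceeds the
#'   configured threshold the fit is flagged (\code{converged = FALSE})
#'   with a warning, never silently.
#' @export
fit_model <- function(datasets, model_type, network = NULL,
                      priors = hyper_priors(), control) {
  stopifnot(inherits(control, "mcmc_control"))
  model_type <- match.arg(model_type, c("glm", "car", "mcar_dt", "mcar_sp"))
  N <- validate_datasets(datasets, model_type)
  if (model_type != "glm") {
    if (is.null(network)) stop(model_type, " requires a port network")
    network <- as_port_network(network)
    if (length(network$ports) != N)
      stop("network has ", length(network$ports),
           " ports but data have ", N)
    W <- network$W
    M <- diag(network$row_sums, N) - W
    meig <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  } else {
    W <- matrix(0, 0, 0); meig <- numeric(0)
  }

  # sample on the centered-covariate scale (decorrelates the intercept
  # from the slopes); draws are shifted back afterwards
  xbars <- lapply(datasets, function(d) {
    Xm <- as.matrix(d$X)
    if (ncol(Xm)) colMeans(Xm) else numeric(0)
  })
  cdatasets <- lapply(seq_along(datasets), function(j) {
    d <- datasets[[j]]
    Xm <- as.matrix(d$X)
    if (ncol(Xm)) Xm <- sweep(Xm, 2, xbars[[j]])
    list(family_code = family_code(d$family), y = as.numeric(d$y),
         n = if (is.null(d$n)) NULL else as.numeric(d$n),
         X = cbind(`(Intercept)` = 1, Xm),
         sigma = if (is.null(d$sigma)) 1 else d$sigma)
  })
  init_coef <- lapply(seq_along(datasets), function(j) {
    d <- datasets[[j]]
    a0 <- switch(d$family,
      binomial = stats::qlogis((sum(d$y) + 0.5) / (sum(d$n) + 1)),
      poisson = log(mean(d$y) + 0.01),
      gaussian = mean(d$y))
    c(a0, rep(0, ncol(as.matrix(d$X))))
  })
  init <- list(coef = init_coef, lam = 0.5, Lambda = diag(length(datasets)))
  cpriors <- list(beta_prec = priors$beta_prec,
                  tau_shape = priors$tau_shape, tau_rate = priors$tau_rate,
                  wishart_df = priors$wishart_df,
                  wishart_scale = priors$wishart_scale)
  mt_code <- if (model_type == "glm") 0L else
    if (model_type == "car") 1L else 2L

  set.seed(control$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, control$n_chains)
  pn <- param_names_for(datasets, model_type, N)
  chains <- vector("list", control$n_chains)
  accept <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    set.seed(chain_seeds[ch])
    res <- .run_mcmc_chain(cdatasets, mt_code, W, meig, cpriors,
                           control$n_warmup, control$n_iter,
                           control$thin, init)
    draws <- res$draws
    colnames(draws) <- pn
    for (j in seq_along(datasets)) {
      if (!length(xbars[[j]])) next
      lab <- datasets[[j]]$label
      bcols <- paste0("beta_", lab, "_", colnames(as.matrix(datasets[[j]]$X)))
      acol <- paste0("alpha_", lab)
      draws[, acol] <- draws[, acol] -
        draws[, bcols, drop = FALSE] %*% xbars[[j]]
    }
    chains[[ch]] <- draws
    accept[[ch]] <- c(theta = res$accept_theta, lam = res$accept_lam)
  }

  out <- structure(
    list(chains = chains, param_names = pn, model_type = model_type,
         datasets = datasets, network = network, priors = priors,
         control = control, chain_seeds = chain_seeds,
         acceptance = accept, N = N,
         labels = vapply(datasets, `[[`, "", "label")),
    class = "posterior_samples")
  if (control$n_chains >= 2L) {
    diag_rep <- run_diagnostics(out)
    out$diagnostics <- diag_rep
    out$converged <- diag_rep$pass
    if (!diag_rep$pass)
      warning("convergence flag: max split R-hat ",
              format(diag_rep$max_rhat, digits = 4), " exceeds ",
              control$rhat_threshold)
  } else {
    out$converged <- NA
  }
  out
}

#' Fit a model specification to port data
#'
#' High-level wrapper: assembles the likelihood datasets for a
#' \code{\link{model_spec}} via \code{\link{build_datasets}} and calls
#' \code{\link{fit_model}}.
#'
#' @param port_data object from \code{\link{read_port_table}} or
#'   \code{\link{simulate_dataset}}.
#' @param spec a \code{model_spec}.
#' @inheritParams fit_model
#' @export
fit <- function(port_data, spec, priors = hyper_priors(), control) {
  datasets <- build_datasets(port_data, spec)
  network <- if (spec$model_type == "glm") NULL else port_data$network
  out <- fit_model(datasets, spec$model_type, network, priors, control)
  out$spec <- spec
  out
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples:", x$model_type, "model,",
      length(x$chains), "chain(s) x", nrow(x$chains[[1]]), "draws,",
      length(x$param_names), "parameters\n")
  if (!is.null(x$diagnostics))
    cat("  max split R-hat:", format(x$diagnostics$max_rhat, digits = 4),
        if (isTRUE(x$converged)) "(converged)" else "(FLAGGED)", "\n")
  invisible(x)
}

#' Stack all chains of a fit into one draw matrix
#'
#' @param samples a \code{posterior_samples} object.
#' @return matrix (total draws x parameters) with named columns.
#' @export
draw_matrix <- function(samples) {
  do.call(rbind, samples$chains)
}

#' Posterior summary table
#'
#' @param object a \code{posterior_samples} object.
#' @param probs quantiles to report.
#' @param ... unused.
#' @return data.frame with mean, sd and quantiles per parameter.
#' @export
summary.posterior_samples <- function(object, probs = c(0.025, 0.975), ...) {
  dm <- draw_matrix(object)
  qs <- t(apply(dm, 2, stats::quantile, probs = probs))
  out <- data.frame(parameter = colnames(dm), mean = colMeans(dm),
                    sd = apply(dm, 2, stats::sd), qs,
                    row.names = NULL, check.names = FALSE)
  names(out)[4:(3 + length(probs))] <- paste0("q", probs * 100)
  out
}
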