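#' Deviance information criterion with per-dataset local components
#'
#' DIC = D-bar + p_D, with D-bar the posterior mean deviance and
#' p_D = D-bar - D(plug-in). The plug-in deviance is evaluated at the
#' posterior mean of the likelihood-level parameters (the detection
#' probability p or the Poisson mean lambda per port), the convention
#' used with latent Gaussian models. For joint models each dataset's
#' deviance terms give a local DIC (local D-bar_j + local p_Dj), and the
#' local components sum to the total by construction.
#'
#' @param samples a \code{posterior_samples} object.
#' @param plugin \code{"linkpar"} (default: posterior mean of p /
#'   lambda) or \code{"eta"} (posterior mean of the linear predictor).
#' @return object of class \code{model_score} with \code{dic},
#'   \code{p_d}, \code{dbar}, and a \code{local} data.frame (one row per
#'   dataset).
#' @export
compute_dic <- function(samples, plugin = c("linkpar", "eta")) {
  plugin <- match.arg(plugin)
  ll <- pointwise_loglik(samples)
  if (nrow(ll[[1]]) == 0) stop("no posterior draws")
  local <- lapply(seq_along(ll), function(j) {
    lj <- ll[[j]]
    d <- samples$datasets[[j]]
    dbar <- mean(-2 * rowSums(lj))
    if (plugin == "linkpar") {
      mp <- attr(lj, "mean_linkpar")
    } else {
      # plug in the posterior-mean linear predictor instead
      mp <- switch(d$family,
        binomial = stats::plogis(mean_eta(samples, j)),
        poisson = exp(mean_eta(samples, j)),
        gaussian = mean_eta(samples, j))
    }
    dhat <- switch(d$family,
      binomial = -2 * sum(stats::dbinom(d$y, d$n, mp, log = TRUE)),
      poisson = -2 * sum(stats::dpois(d$y, mp, log = TRUE)),
      gaussian = -2 * sum(stats::dnorm(d$y, mp,
        if (is.null(d$sigma)) 1 else d$sigma, log = TRUE)))
    p_d <- dbar - dhat
    data.frame(dataset = d$label, dbar = dbar, dhat = dhat,
               p_d = p_d, dic = dbar + p_d)
  })
  local <- do.call(rbind, local)
  structure(list(dic = sum(local$dic), p_d = sum(local$p_d),
                 dbar = sum(local$dbar), local = local,
                 plugin = plugin),
            class = "model_score")
}

mean_eta <- function(samples, j) {
  dm <- draw_matrix(samples)
  d <- samples$datasets[[j]]
  cn <- colnames(as.matrix(d$X))
  cols <- c(paste0("alpha_", d$label),
            if (length(cn)) paste0("beta_", d$label, "_", cn))
  eta <- dm[, cols, drop = FALSE] %*% t(cbind(1, as.matrix(d$X)))
  if (samples$model_type != "glm")
    eta <- eta + dm[, paste0("theta_", d$label, "[",
                             seq_len(samples$N), "]"), drop = FALSE]
  colMeans(eta)
}

#' Widely applicable information criterion
#'
#' WAIC = -2 * sum_i [ log mean_draws lik_i - var_draws loglik_i ],
#' from the pointwise posterior log-likelihood matrix; reported in the
#' same deviance units as DIC, with per-dataset local components.
#'
#' @param samples a \code{posterior_samples} object.
#' @return \code{model_score} with \code{waic}, \code{p_waic},
#'   \code{lppd} and a \code{local} data.frame.
#' @export
compute_waic <- function(samples) {
  ll <- pointwise_loglik(samples)
  if (nrow(ll[[1]]) == 0) stop("no posterior draws")
  local <- lapply(seq_along(ll), function(j) {
    lj <- ll[[j]]
    S <- nrow(lj)
    # log mean exp, stabilized
    lppd_i <- apply(lj, 2, function(v) {
      mx <- max(v); mx + log(mean(exp(v - mx)))
    })
    p_i <- apply(lj, 2, stats::var)
    data.frame(dataset = samples$labels[j], lppd = sum(lppd_i),
               p_waic = sum(p_i),
               waic = -2 * (sum(lppd_i) - sum(p_i)))
  })
  local <- do.call(rbind, local)
  structure(list(waic = sum(local$waic), p_waic = sum(local$p_waic),
                 lppd = sum(local$lppd), local = local),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  if (!is.null(x$dic))
    cat("DIC:", format(x$dic, digits = 6),
        " (p_D =", format(x$p_d, digits = 4), ")\n")
  if (!is.null(x$waic))
    cat("WAIC:", format(x$waic, digits = 6),
        " (p_WAIC =", format(x$p_waic, digits = 4), ")\n")
  if (nrow(x$local) > 1) {
    cat("local components:\n")
    print(x$local, row.names = FALSE, digits = 6)
  }
  invisible(x)
}

#' Is a covariate retained by the stepwise DIC rule?
#'
#' A covariate contributes if removing it raises the DIC by strictly
#' more than the threshold: DIC(reduced) - DIC(full) > 2. A rise of
#' exactly 2 excludes the covariate.
#'
#' @param dic_full DIC of the full model.
#' @param dic_reduced DIC of the model with the covariate removed.
#' @param threshold retention threshold (default 2).
#' @return logical.
#' @export
covariate_retained <- function(dic_full, dic_reduced, threshold = 2) {
  (dic_reduced - dic_full) > threshold
}

#' Stepwise covariate selection by leave-one-out DIC comparison
#'
#' Fits the full model and, for each covariate, the model with that
#' covariate removed. A covariate is retained iff its removal increases
#' the DIC by strictly more than \code{threshold}. WAIC is recorded
#' alongside as a cross-check. Only single-covariate reductions are
#' compared.
#'
#' @param port_data data object (see \code{\link{read_port_table}} /
#'   \code{\link{simulate_dataset}}).
#' @param spec the full \code{\link{model_spec}} (its covariate set is
#'   the candidate pool).
#' @param priors a \code{\link{hyper_priors}}.
#' @param control an \code{\link{mcmc_control}}; reduction fits reuse
#'   its seed offset by the reduction index.
#' @param threshold DIC-increase threshold for retention (default 2).
#' @param require_convergence abort (with the partial trace attached to
#'   the condition) if any component fit fails its R-hat flag.
#' @return list with \code{spec} (the selected specification),
#'   \code{trace} (data.frame: candidate set, DIC, WAIC, decision) and
#'   \code{fits} (the full-model fit).
#' @export
stepwise_select <- function(port_data, spec, priors = hyper_priors(),
                            control, threshold = 2,
                            require_convergence = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  full_fit <- fit(port_data, spec, priors, control)
  trace <- data.frame(model = "full",
                      covariates = paste(spec$covariates, collapse = "+"),
                      dic = compute_dic(full_fit)$dic,
                      waic = compute_waic(full_fit)$waic,
                      delta_dic = 0, decision = "reference",
                      stringsAsFactors = FALSE)
  check_conv <- function(f, what) {
    if (require_convergence && isFALSE(f$converged))
      stop(structure(class = c("stepwise_abort", "error", "condition"),
                     message = paste0("non-converged fit for ", what,
                                      "; selection aborted"),
                     call = sys.call(-1), trace = trace))
  }
  check_conv(full_fit, "full model")
  kept <- character(0)
  for (ci in seq_along(spec$covariates)) {
    cv <- spec$covariates[ci]
    red_spec <- spec
    red_spec$covariates <- setdiff(spec$covariates, cv)
    red_control <- control
    red_control$seed <- control$seed + ci
    red_fit <- fit(port_data, red_spec, priors, red_control)
    check_conv(red_fit, paste("reduction without", cv))
    dic_red <- compute_dic(red_fit)$dic
    waic_red <- compute_waic(red_fit)$waic
    keep <- covariate_retained(trace$dic[1], dic_red, threshold)
    if (keep) kept <- c(kept, cv)
    trace <- rbind(trace, data.frame(
      model = paste0("drop_", cv),
      covariates = paste(red_spec$covariates, collapse = "+"),
      dic = dic_red, waic = waic_red,
      delta_dic = dic_red - trace$dic[1],
      decision = if (keep) "covariate kept" else "covariate dropped"))
  }
  sel <- spec
  sel$covariates <- kept
  list(spec = sel, trace = trace, fits = full_fit)
}

#' Model-comparison table across fitted models
#'
#' Rows are models, columns the per-dataset local DIC/WAIC and totals —
#' the shape used to compare separate and joint models.
#'
#' @param fits named list of \code{posterior_samples} objects.
#' @return data.frame.
#' @export
comparison_table <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    sc <- compute_dic(fits[[nm]])
    wc <- compute_waic(fits[[nm]])
    loc <- sc$local
    data.frame(model = nm,
               dataset = loc$dataset,
               local_dic = loc$dic,
               local_waic = wc$local$waic,
               total_dic = sc$dic,
               total_waic = wc$waic)
  })
  do.call(rbind, rows)
}
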