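#' Prepare covariates for the introduction-risk models
#'
#' Imported-container counts enter the linear predictors on the log
#' scale, reflecting the propagule-pressure assumption that risk grows
#' sub-linearly in logistics volume. Zero-volume ports are kept finite
#' through a pseudocount: log_NC = log(NC + pseudocount). Minimum annual
#' temperature passes through unchanged unless standardization is
#' requested.
#'
#' @param nc numeric vector or matrix of imported-container counts
#'   (containers/year), ports in rows, species in columns. Must be >= 0.
#' @param mt numeric vector of annual minimum temperature (deg C), one
#'   value per port.
#' @param pseudocount added to NC before the log; default 1.
#' @param standardize if TRUE, z-score log_NC and MT (columnwise).
#' @return list of class \code{covariate_table} with \code{nc},
#'   \code{log_nc}, \code{mt}.
#' @export
prepare_covariates <- function(nc, mt, pseudocount = 1, standardize = FALSE) {
  ncm <- as.matrix(nc)
  if (any(!is.finite(ncm)) || any(ncm < 0))
    stop("container counts NC must be finite and nonnegative")
  if (length(mt) != nrow(ncm))
    stop("mt must have one value per port")
  log_nc <- log(ncm + pseudocount)
  mt <- as.numeric(mt)
  if (standardize) {
    log_nc <- scale(log_nc)
    attr(log_nc, "scaled:center") <- NULL
    attr(log_nc, "scaled:scale") <- NULL
    mt <- as.numeric(scale(mt))
  }
  structure(list(nc = ncm, log_nc = log_nc, mt = mt),
            class = "covariate_table")
}

#' Linear predictor for one dataset-species pair
#'
#' eta_i = intercept + sum_l beta_l x_il + theta_i. For the survey
#' (binomial) model the detection probability is p = plogis(eta); for
#' the presence-only (Poisson) model the expected count is exp(eta).
#'
#' @param intercept scalar intercept.
#' @param beta named numeric vector of coefficients; names must match
#'   columns of \code{X}.
#' @param X design matrix of covariates (no intercept column), ports in
#'   rows; column names identify the covariates.
#' @param theta latent network effects, one per port (0 for a GLM).
#' @return numeric vector eta of length N.
#' @export
linear_predictor <- function(intercept, beta, X, theta = 0) {
  X <- as.matrix(X)
  if (length(beta) != ncol(X))
    stop("beta has length ", length(beta),
         " but the design matrix has ", ncol(X), " covariate(s)")
  if (!is.null(names(beta)) && !is.null(colnames(X)) &&
      !identical(names(beta), colnames(X)))
    stop("beta names do not match covariate columns")
  eta <- rep(intercept, nrow(X)) +
    if (ncol(X) > 0) drop(X %*% beta) else 0
  eta + theta
}

#' Binomial log-likelihood of the port-survey data
#'
#' Detections Y_i out of n_i surveys with logit(p_i) = eta_i. Written
#' directly from the binomial pmf (log-choose plus log-odds terms) with
#' care at the saturation limits p -> 0, 1.
#'
#' @param y detections per port (surveys with >= 1 detection).
#' @param n surveys per port.
#' @param eta linear predictor (logit scale).
#' @return total log-likelihood (scalar).
#' @export
survey_loglik <- function(y, n, eta) {
  stopifnot(length(y) == length(n), length(eta) == length(y))
  if (any(y < 0) || any(y > n))
    stop("detection counts must satisfy 0 <= y <= n")
  if (any(n < 1)) stop("each port needs at least one survey")
  # log p = -log(1 + e^-eta), log(1-p) = -log(1 + e^eta), numerically safe
  log_p <- -log1p(exp(-eta))
  log_q <- -log1p(exp(eta))
  log_p[eta > 700] <- 0; log_q[eta > 700] <- -eta[eta > 700]
  log_q[eta < -700] <- 0; log_p[eta < -700] <- eta[eta < -700]
  sum(lchoose(n, y) + y * log_p + (n - y) * log_q)
}

#' Poisson log-likelihood of the presence-only data
#'
#' Introduction-record counts Y_i with log(lambda_i) = eta_i:
#' sum_i [ Y_i eta_i - exp(eta_i) - log(Y_i!) ].
#'
#' @param y nonnegative integer record counts per port.
#' @param eta linear predictor (log scale).
#' @return total log-likelihood (scalar).
#' @export
presence_only_loglik <- function(y, eta) {
  stopifnot(length(y) == length(eta))
  if (any(y < 0) || any(y != round(y)))
    stop("presence-only counts must be nonnegative integers")
  sum(y * eta - exp(eta) - lgamma(y + 1))
}

#' Risk surface from a linear predictor
#'
#' @param eta linear predictor.
#' @param family \code{"binomial"} (detection probability, inverse
#'   logit) or \code{"poisson"} (expected records, exp).
#' @return numeric vector: p in (0,1) or lambda > 0.
#' @export
risk_surface <- function(eta, family = c("binomial", "poisson")) {
  family <- match.arg(family)
  if (family == "binomial") stats::plogis(eta) else exp(eta)
}
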