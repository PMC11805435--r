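#' Split R-hat for one parameter
#'
#' Potential scale reduction computed after splitting each chain in
#' half, so within-chain drift also registers as non-convergence.
#'
#' @param chains_mat matrix, iterations x chains, one sampled scalar.
#' @return split R-hat (NA for a parameter with zero variance).
#' @export
split_rhat <- function(chains_mat) {
  chains_mat <- as.matrix(chains_mat)
  n <- nrow(chains_mat)
  half <- floor(n / 2)
  sp <- cbind(chains_mat[seq_len(half), , drop = FALSE],
              chains_mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size for one parameter
#'
#' Multi-chain ESS from averaged autocorrelations with Geyer's initial
#' positive-sequence truncation.
#'
#' @inheritParams split_rhat
#' @return estimated effective sample size (NA for zero variance).
#' @export
ess_basic <- function(chains_mat) {
  chains_mat <- as.matrix(chains_mat)
  n <- nrow(chains_mat); m <- ncol(chains_mat)
  vars <- apply(chains_mat, 2, stats::var)
  W <- mean(vars)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  means <- colMeans(chains_mat)
  B_over_n <- if (m > 1) stats::var(means) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  max_lag <- min(n - 1, 500L)
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(chains_mat[, j], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  acov <- as.matrix(acov)
  rho <- 1 - (W - rowMeans(acov)) / var_plus  # lag 0 row gives rho ~ W/var+
  rho[1] <- 1
  # Geyer initial positive sequence on paired sums
  s <- 0; t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t + 1] + if (t + 2 <= length(rho)) rho[t + 2] else 0
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

#' Convergence diagnostics for a fitted model
#'
#' Split R-hat and effective sample size for every sampled scalar, plus
#' acceptance-rate summaries for the Metropolis moves, with a pass/fail
#' flag at the control's R-hat threshold. Requires at least two chains.
#'
#' @param samples a \code{posterior_samples} object.
#' @param rhat_threshold overrides the threshold stored in the fit's
#'   control when given.
#' @return list of class \code{diagnostics_report}: \code{table}
#'   (parameter, rhat, ess), \code{max_rhat}, \code{pass},
#'   \code{acceptance}.
#' @export
run_diagnostics <- function(samples, rhat_threshold = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (length(samples$chains) < 2L)
    stop("split R-hat requires at least 2 chains")
  thr <- if (is.null(rhat_threshold))
    samples$control$rhat_threshold else rhat_threshold
  pn <- samples$param_names
  rhat <- numeric(length(pn)); ess <- numeric(length(pn))
  for (k in seq_along(pn)) {
    cm <- sapply(samples$chains, function(ch) ch[, k])
    rhat[k] <- split_rhat(cm)
    ess[k] <- ess_basic(cm)
  }
  tab <- data.frame(parameter = pn, rhat = rhat, ess = ess)
  max_rhat <- suppressWarnings(max(rhat, na.rm = TRUE))
  structure(list(table = tab, max_rhat = max_rhat,
                 pass = is.finite(max_rhat) && max_rhat <= thr,
                 threshold = thr,
                 acceptance = samples$acceptance),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("diagnostics: max split R-hat", format(x$max_rhat, digits = 4),
      if (x$pass) "<= " else "> ", x$threshold,
      if (x$pass) "(pass)\n" else "(FLAGGED)\n")
  cat("  min ESS:", format(suppressWarnings(min(x$table$ess, na.rm = TRUE)),
                           digits = 4), "\n")
  invisible(x)
}
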