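#' Leroux structure matrix R(lambda)
#'
#' The Leroux CAR prior interpolates between independence (lambda = 0)
#' and the intrinsic CAR (lambda -> 1) through the structure matrix
#' R(lambda) = (1 - lambda) I + lambda (diag(W1) - W). For lambda < 1
#' and a valid weight matrix R(lambda) is symmetric positive definite,
#' so the joint prior is proper.
#'
#' @param network a \code{port_network} (or symmetric weight matrix).
#' @param lam spatial-dependence parameter, in [0, 1).
#' @return N x N symmetric positive-definite structure matrix.
#' @export
leroux_structure <- function(network, lam) {
  network <- as_port_network(network)
  check_lambda(lam)
  W <- network$W
  N <- nrow(W)
  (1 - lam) * diag(N) + lam * (diag(network$row_sums, N) - W)
}

#' Leroux precision matrix
#'
#' Q = tau * R(lambda), the precision of the joint zero-mean Gaussian
#' prior theta ~ N(0, Q^-1).
#'
#' @inheritParams leroux_structure
#' @param tau precision parameter, > 0.
#' @return object of class \code{precision_matrix} with fields \code{Q}
#'   and \code{structure} (\code{"leroux"}).
#' @export
leroux_precision <- function(network, lam, tau) {
  check_tau(tau)
  Q <- tau * leroux_structure(network, lam)
  new_precision(Q, "leroux")
}

#' Full conditional of one port's random effect under the Leroux prior
#'
#' theta_i | theta_(-i) is normal with mean
#' lambda * sum(w_ii' theta_i') / (lambda * sum(w_ii') + 1 - lambda) and
#' variance tau^-1 / (lambda * sum(w_ii') + 1 - lambda). An isolated
#' port (zero row sum) degenerates to N(0, tau^-1 / (1 - lambda)).
#'
#' @param theta numeric vector of length N.
#' @param i port index (1-based).
#' @inheritParams leroux_precision
#' @return list with \code{mean} and \code{variance}.
#' @export
leroux_conditional <- function(theta, i, network, lam, tau) {
  network <- as_port_network(network)
  check_lambda(lam); check_tau(tau)
  N <- length(network$ports)
  stopifnot(length(theta) == N, i >= 1, i <= N)
  w <- network$W[i, ]
  denom <- lam * sum(w) + 1 - lam
  list(mean = lam * sum(w * theta) / denom,
       variance = 1 / (tau * denom))
}

#' Cross-dataset precision for the multivariate CAR prior
#'
#' The two stacked CAR fields share the structure R(lambda); their
#' cross-dataset covariance is
#' Lambda^-1 = [[1/tau1, rho/sqrt(tau1 tau2)],
#'              [rho/sqrt(tau1 tau2), 1/tau2]],
#' so rho is the correlation coefficient between the datasets' random
#' effects and tau1, tau2 their marginal precisions.
#'
#' @param tau1,tau2 per-dataset precisions, > 0.
#' @param rho cross-dataset correlation, in (-1, 1).
#' @return object of class \code{cross_precision} with fields
#'   \code{tau1}, \code{tau2}, \code{rho}, \code{Lambda} (the 2 x 2
#'   precision) and \code{Lambda_inv}.
#' @export
cross_precision <- function(tau1, tau2, rho) {
  check_tau(tau1); check_tau(tau2)
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("rho must lie in (-1, 1)")
  Lambda_inv <- matrix(c(1 / tau1, rho / sqrt(tau1 * tau2),
                         rho / sqrt(tau1 * tau2), 1 / tau2), 2, 2)
  Lambda <- solve(Lambda_inv)
  structure(list(tau1 = tau1, tau2 = tau2, rho = rho,
                 Lambda = Lambda, Lambda_inv = Lambda_inv),
            class = "cross_precision")
}

#' Convert a 2 x 2 precision matrix Lambda to (tau1, tau2, rho)
#'
#' Inverts the parameterization of \code{\link{cross_precision}}:
#' tau_j = 1 / (Lambda^-1)_jj and rho = correlation implied by
#' Lambda^-1.
#'
#' @param Lambda symmetric positive-definite 2 x 2 matrix.
#' @return a \code{cross_precision}.
#' @export
cross_precision_from_Lambda <- function(Lambda) {
  stopifnot(is.matrix(Lambda), all(dim(Lambda) == 2))
  V <- solve(Lambda)
  cross_precision(1 / V[1, 1], 1 / V[2, 2],
                  V[1, 2] / sqrt(V[1, 1] * V[2, 2]))
}

#' Multivariate CAR (MCAR) precision matrix
#'
#' Joint precision of the stacked field Theta = [theta_1', theta_2']':
#' Q = Lambda (x) R(lambda), the Kronecker product of the cross-dataset
#' precision and the shared Leroux structure, so that
#' Theta ~ N(0, Lambda^-1 (x) R(lambda)^-1).
#'
#' @inheritParams leroux_structure
#' @param cross a \code{cross_precision}.
#' @return \code{precision_matrix} of dimension 2N x 2N, structure
#'   \code{"mcar"}.
#' @export
mcar_precision <- function(network, lam, cross) {
  stopifnot(inherits(cross, "cross_precision"))
  ev <- eigen(cross$Lambda, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Lambda must be positive definite")
  R <- leroux_structure(network, lam)
  new_precision(kronecker(cross$Lambda, R), "mcar")
}

new_precision <- function(Q, structure) {
  structure(list(Q = Q, structure = structure), class = "precision_matrix")
}

#' @export
print.precision_matrix <- function(x, ...) {
  cat(sprintf("%s precision matrix, %d x %d\n",
              x$structure, nrow(x$Q), ncol(x$Q)))
  invisible(x)
}

get_Q <- function(Q) {
  if (inherits(Q, "precision_matrix")) Q$Q else as.matrix(Q)
}

#' Log-density of a zero-mean Gaussian Markov random field
#'
#' Evaluates -(d/2) log(2 pi) + (1/2) log det Q - (1/2) theta' Q theta
#' through a Cholesky factorization of the precision (stable for the
#' dense network sizes used here, up to a few hundred ports).
#'
#' @param theta numeric vector.
#' @param Q a \code{precision_matrix} or plain symmetric PD matrix.
#' @return log-density (scalar).
#' @export
gmrf_logpdf <- function(theta, Q) {
  Qm <- get_Q(Q)
  d <- nrow(Qm)
  if (length(theta) != d)
    stop("theta has length ", length(theta), " but Q is ", d, " x ", d)
  U <- tryCatch(chol(Qm), error = function(e)
    stop("precision matrix is not positive definite"))
  -0.5 * d * log(2 * pi) + sum(log(diag(U))) -
    0.5 * drop(crossprod(theta, Qm %*% theta))
}

#' Sample from a zero-mean GMRF given its precision matrix
#'
#' Draws theta ~ N(0, Q^-1) by back-substitution against the upper
#' Cholesky factor of Q. Reproducible: the same seed yields identical
#' draws.
#'
#' @param Q precision matrix (or \code{precision_matrix}).
#' @param n_draws number of independent draws.
#' @param seed integer RNG seed (mandatory).
#' @return matrix of dimension \code{n_draws} x d.
#' @export
gmrf_sample <- function(Q, n_draws = 1, seed) {
  if (missing(seed)) stop("a seed is required for gmrf_sample")
  Qm <- get_Q(Q)
  d <- nrow(Qm)
  U <- tryCatch(chol(Qm), error = function(e)
    stop("precision matrix is not positive definite"))
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_draws * d), nrow = d)
  t(backsolve(U, Z))
}

check_lambda <- function(lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) ||
      lam < 0 || lam >= 1)
    stop("lambda must lie in [0, 1)")
  invisible(lam)
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a positive scalar")
  invisible(tau)
}
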