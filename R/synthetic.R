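#' Scenario configuration for the synthetic-data generator
#'
#' Defaults mirror the scale of the motivating study system: 65 ports
#' surveyed 13-20 times each, a hub-and-spoke container network with two
#' weakly connected clusters, heavy-tailed (log-normal) import volumes
#' correlated with network degree, a north-south minimum-temperature
#' gradient, survey detection probabilities averaging around 2%, and
#' presence-only record counts of order one per port. True latent
#' effects follow the MCAR prior with moderate dependence and
#' cross-dataset correlation (lambda 0.5, tau 2, rho 0.5 by default).
#'
#' @param n_ports number of ports (default 65).
#' @param n_hubs number of hub ports (default 4, split over 2 clusters).
#' @param surveys_range min and max surveys per port (default 13-20).
#' @param species species ids (two by default).
#' @param intercept_survey,intercept_po true intercepts (logit / log
#'   scale).
#' @param beta_nc,beta_mt true coefficients of log_NC and MT.
#' @param lam,tau1,tau2,rho true Leroux/MCAR hyperparameters (tau1:
#'   survey field, tau2: presence-only field).
#' @param spoke_edge_prob probability a within-cluster spoke-spoke pair
#'   is connected (0 gives a pure hub-and-spoke graph).
#' @param cross_cluster_prob probability a cross-cluster spoke-spoke
#'   pair is connected (small: the clusters are rarely connected).
#' @param mt_noise sd of the temperature noise around the latitudinal
#'   gradient (0 gives an exactly linear gradient).
#' @param latent if FALSE the latent fields are identically zero (GLM
#'   truth).
#' @param seed integer seed (mandatory).
#' @return list of class \code{scenario_config}.
#' @export
scenario_config <- function(n_ports = 65, n_hubs = 4,
                            surveys_range = c(13, 20),
                            species = c("invicta", "geminata"),
                            intercept_survey = -7.2, intercept_po = -3.5,
                            beta_nc = 0.5, beta_mt = 0,
                            lam = 0.5, tau1 = 2, tau2 = 2, rho = 0.5,
                            spoke_edge_prob = 0.15,
                            cross_cluster_prob = 0.01,
                            mt_noise = 1, latent = TRUE, seed) {
  if (missing(seed)) stop("scenario_config requires a seed")
  if (n_hubs >= n_ports) stop("n_hubs must be smaller than n_ports")
  if (n_hubs < 1) stop("need at least one hub")
  stopifnot(length(surveys_range) == 2, surveys_range[1] >= 1,
            surveys_range[2] >= surveys_range[1])
  check_lambda(lam); check_tau(tau1); check_tau(tau2)
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  structure(as.list(environment()), class = "scenario_config")
}

#' Generate a hub-and-spoke container-flow edge list
#'
#' Hubs are split over two clusters (eastern / western, mimicking a
#' national container network organized around a few large ports). Every
#' spoke attaches to the hubs of its cluster with heavy-tailed
#' (log-normal) volumes; hub-hub volumes are large; spoke-spoke edges
#' are sparse within a cluster and nearly absent across clusters, so the
#' resulting weight matrix is sparse.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return data.frame edge list (\code{origin}, \code{destination},
#'   \code{volume}) plus attributes \code{roster} and \code{cluster}.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  N <- config$n_ports; H <- config$n_hubs
  roster <- sprintf("P%02d", seq_len(N))
  hubs <- seq_len(H)
  n_clusters <- if (H >= 2) 2L else 1L
  hub_cluster <- rep(seq_len(n_clusters), length.out = H)
  spoke_cluster <- sample(rep(seq_len(n_clusters),
                              length.out = N - H))
  cluster <- c(hub_cluster, spoke_cluster)
  edges <- list(); k <- 0
  add <- function(i, j, vol) {
    k <<- k + 1
    edges[[k]] <<- data.frame(origin = roster[i], destination = roster[j],
                              volume = vol)
  }
  # hub-hub: large volumes, same-cluster larger than cross-cluster
  if (H >= 2) {
    for (i in 1:(H - 1)) for (j in (i + 1):H) {
      ml <- if (cluster[i] == cluster[j]) 10.5 else 8.5
      add(i, j, stats::rlnorm(1, ml, 0.5))
    }
  }
  # hub-spoke: every spoke attaches to all hubs of its cluster
  for (s in (H + 1):N) {
    for (h in hubs[hub_cluster == cluster[s]])
      add(h, s, stats::rlnorm(1, 6.5, 1.5))
  }
  # spoke-spoke: sparse within cluster, nearly absent across
  if (N - H >= 2) {
    sp <- (H + 1):N
    for (a in seq_along(sp)[-length(sp)]) for (b in (a + 1):length(sp)) {
      i <- sp[a]; j <- sp[b]
      pr <- if (cluster[i] == cluster[j]) config$spoke_edge_prob
            else config$cross_cluster_prob
      if (stats::runif(1) < pr) add(i, j, stats::rlnorm(1, 4, 1))
    }
  }
  out <- do.call(rbind, edges)
  attr(out, "roster") <- roster
  attr(out, "cluster") <- cluster
  out
}

#' Generate synthetic covariates
#'
#' Import volumes NC are log-normal and positively tied to each port's
#' weighted network degree (large ports import more); the annual minimum
#' temperature follows a monotone north-south gradient in port order
#' with Gaussian noise.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param network a \code{port_network} built from
#'   \code{\link{generate_network}} output.
#' @return a \code{covariate_table} (log_NC per species, MT), with the
#'   raw NC matrix in \code{$nc}.
#' @export
generate_covariates <- function(config, network) {
  stopifnot(inherits(config, "scenario_config"))
  network <- as_port_network(network)
  set.seed(config$seed + 1L)
  N <- length(network$ports)
  wdeg <- network$row_sums
  z <- as.numeric(scale(wdeg))
  if (any(!is.finite(z))) z <- rep(0, N)
  nc <- sapply(config$species, function(sp)
    round(exp(5 + 1.2 * z + stats::rnorm(N, 0, 0.8))))
  colnames(nc) <- config$species
  mt <- seq(-4, 18, length.out = N) +
    stats::rnorm(N, 0, config$mt_noise)
  prepare_covariates(nc, mt)
}

#' Simulate a complete synthetic dataset from the generative model
#'
#' Draws the latent fields Theta from the MCAR prior (one independent
#' stacked survey/presence-only field per species), forms the linear
#' predictors, and draws binomial survey counts and Poisson
#' presence-only counts. The true parameters and latent draws are stored
#' alongside the data.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return object of class \code{port_data} with fields \code{roster},
#'   \code{n_surveys}, \code{det}, \code{po}, \code{covariates},
#'   \code{network}, \code{species} and \code{truth}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  edges <- generate_network(config)
  network <- suppressWarnings(
    port_network(edges, attr(edges, "roster")))
  covariates <- generate_covariates(config, network)
  N <- config$n_ports
  cross <- cross_precision(config$tau1, config$tau2, config$rho)
  theta <- list()
  if (config$latent) {
    Q <- mcar_precision(network, config$lam, cross)
    for (si in seq_along(config$species)) {
      th <- gmrf_sample(Q, 1, seed = config$seed + 100L + si)
      theta[[config$species[si]]] <-
        matrix(as.numeric(th), ncol = 2)  # cols: survey, po
    }
  } else {
    for (sp in config$species)
      theta[[sp]] <- matrix(0, N, 2)
  }
  set.seed(config$seed + 2L)
  n_surveys <- sample(seq(config$surveys_range[1], config$surveys_range[2]),
                      N, replace = TRUE)
  det <- matrix(0L, N, length(config$species),
                dimnames = list(NULL, config$species))
  po <- det
  for (sp in config$species) {
    Xs <- cbind(log_NC = covariates$log_nc[, sp], MT = covariates$mt)
    eta1 <- linear_predictor(config$intercept_survey,
                             c(log_NC = config$beta_nc, MT = config$beta_mt),
                             Xs, theta[[sp]][, 1])
    eta2 <- linear_predictor(config$intercept_po,
                             c(log_NC = config$beta_nc, MT = config$beta_mt),
                             Xs, theta[[sp]][, 2])
    det[, sp] <- stats::rbinom(N, n_surveys, stats::plogis(eta1))
    po[, sp] <- stats::rpois(N, exp(eta2))
  }
  structure(
    list(roster = network$ports, n_surveys = n_surveys, det = det,
         po = po, covariates = covariates, network = network,
         species = config$species,
         truth = list(config = config, theta = theta, cross = cross)),
    class = "port_data")
}

#' @export
print.port_data <- function(x, ...) {
  cat("port_data:", length(x$roster), "ports,",
      paste(x$species, collapse = ", "), "\n")
  cat("  survey detections:", colSums(x$det), "of", sum(x$n_surveys),
      "trials\n")
  if (!is.null(x$po)) cat("  presence-only records:", colSums(x$po), "\n")
  invisible(x)
}

true_value_for <- function(param, config) {
  if (grepl("^beta_.*_log_NC$", param)) return(config$beta_nc)
  if (grepl("^beta_.*_MT$", param)) return(config$beta_mt)
  if (grepl("^alpha_survey", param)) return(config$intercept_survey)
  if (grepl("^alpha_po", param)) return(config$intercept_po)
  switch(param, rho = config$rho, lam = config$lam,
         tau1 = config$tau1, tau2 = config$tau2, tau = config$tau1,
         NA_real_)
}

#' Parameter-recovery experiment over simulated replicates
#'
#' Simulates \code{n_replicates} datasets from a scenario, fits the
#' given model specification to each, and reports per-parameter bias,
#' RMSE and empirical 95% credible-interval coverage against the
#' scenario's true values, with a full manifest of the seeds used.
#' Replicate fit failures are recorded, never silently dropped.
#'
#' @param config a \code{\link{scenario_config}} (its seed anchors the
#'   replicate seeds).
#' @param n_replicates number of simulated replicates (>= 2).
#' @param spec \code{\link{model_spec}} to fit.
#' @param control \code{\link{mcmc_control}} template; replicate r runs
#'   with seed \code{control$seed + r}.
#' @param params parameters to track (default: all fixed effects and
#'   hyperparameters with a defined true value).
#' @param priors hyperpriors.
#' @return list of class \code{recovery_report}: \code{summary}
#'   (data.frame of bias / rmse / coverage per parameter),
#'   \code{estimates} (long data.frame per replicate), \code{seeds},
#'   \code{failures}.
#' @export
recovery_experiment <- function(config, n_replicates, spec, control,
                                params = NULL, priors = hyper_priors()) {
  stopifnot(n_replicates >= 2)
  rows <- list(); failures <- list()
  seeds <- data.frame(replicate = seq_len(n_replicates),
                      data_seed = config$seed + seq_len(n_replicates),
                      fit_seed = control$seed + seq_len(n_replicates))
  for (r in seq_len(n_replicates)) {
    cfg_r <- config; cfg_r$seed <- seeds$data_seed[r]
    ctl_r <- control; ctl_r$seed <- seeds$fit_seed[r]
    res <- tryCatch({
      dat <- simulate_dataset(cfg_r)
      ft <- suppressWarnings(fit(dat, spec, priors, ctl_r))
      sm <- summary(ft)
      if (is.null(params)) {
        tv <- vapply(sm$parameter, true_value_for, 0, config = config)
        params <- sm$parameter[!is.na(tv)]
      }
      sm <- sm[sm$parameter %in% params, ]
      sm$truth <- vapply(sm$parameter, true_value_for, 0, config = config)
      sm$covered <- sm$q2.5 <= sm$truth & sm$truth <= sm$q97.5
      sm$replicate <- r
      sm$converged <- isTRUE(ft$converged)
      sm
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        data.frame(replicate = r, message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  est <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(est, est$parameter), function(g)
    data.frame(parameter = g$parameter[1], truth = g$truth[1],
               n = nrow(g),
               bias = mean(g$mean - g$truth),
               rmse = sqrt(mean((g$mean - g$truth)^2)),
               coverage = mean(g$covered),
               mc_se = stats::sd(g$mean) / sqrt(nrow(g)))))
  rownames(summ) <- NULL
  structure(list(summary = summ, estimates = est, seeds = seeds,
                 failures = if (length(failures))
                   do.call(rbind, failures) else NULL),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report over", max(x$estimates$replicate), "replicates\n")
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.null(x$failures))
    cat("  failures:", nrow(x$failures), "replicate(s)\n")
  invisible(x)
}
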