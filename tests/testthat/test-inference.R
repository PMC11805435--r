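test_that("log-posterior decomposes: CAR at lam 0 = GLM + iid terms", {
  cfg <- quick_scenario(seed = 61)
  dat <- simulate_dataset(cfg)
  spec <- model_spec("car", species = "invicta", datasets = "survey")
  ds <- build_datasets(dat, spec)
  pri <- hyper_priors()
  co <- list(c(-3, 0.4, 0.02))
  # at theta = 0 the likelihood terms coincide, so the car posterior is
  # the glm posterior plus iid-normal theta terms and the tau/lam priors
  th <- matrix(0, 30, 1)
  tau <- 1.7
  lp_car <- log_posterior(list(coef = co, theta = th, tau = tau, lam = 0),
                          ds, "car", dat$network, pri)
  lp_glm <- log_posterior(list(coef = co), ds, "glm", priors = pri)
  iid <- sum(stats::dnorm(th, 0, sqrt(1 / tau), log = TRUE)) +
    stats::dgamma(tau, 1, scale = 100, log = TRUE) +
    stats::dunif(0, 0, 1, log = TRUE)
  expect_equal(lp_car, lp_glm + iid, tolerance = 1e-9)
})

test_that("log-posterior equals an independent straight-line oracle", {
  cfg <- quick_scenario(seed = 62)
  dat <- simulate_dataset(cfg)
  spec <- model_spec("mcar_dt", species = "geminata",
                     datasets = c("survey", "po"), covariates = "log_NC")
  ds <- build_datasets(dat, spec)
  pri <- hyper_priors()
  co <- list(c(-3.5, 0.45), c(-1.2, 0.3))
  th <- matrix(stats::rnorm(60, 0, 0.4), ncol = 2)
  cr <- cross_precision(1.4, 2.2, 0.35)
  lam <- 0.55
  got <- log_posterior(list(coef = co, theta = th, cross = cr, lam = lam),
                       ds, "mcar_dt", dat$network, pri)
  # oracle: rebuilt term by term with stats:: densities
  eta1 <- co[[1]][1] + co[[1]][2] * ds[[1]]$X[, "log_NC"] + th[, 1]
  eta2 <- co[[2]][1] + co[[2]][2] * ds[[2]]$X[, "log_NC"] + th[, 2]
  want <- sum(stats::dbinom(ds[[1]]$y, ds[[1]]$n, stats::plogis(eta1),
                            log = TRUE)) +
    sum(stats::dpois(ds[[2]]$y, exp(eta2), log = TRUE)) +
    sum(stats::dnorm(unlist(co), 0, sqrt(1000), log = TRUE)) +
    mvn_logpdf_dense(as.numeric(th),
                     kronecker(cr$Lambda_inv,
                               solve(leroux_structure(dat$network, lam)))) +
    dwishart_log(cr$Lambda, 4, diag(2)) + stats::dunif(lam, 0, 1, log = TRUE)
  expect_equal(got, want, tolerance = 1e-8)
  # outside support
  expect_identical(
    log_posterior(list(coef = co, theta = th, cross = cr, lam = 1.2),
                  ds, "mcar_dt", dat$network, pri), -Inf)
  expect_identical(
    log_posterior(list(coef = co, theta = th, tau = -1, lam = 0.5),
                  list(ds[[1]]), "car", dat$network, pri), -Inf)
})

test_that("empty-data GLM log-posterior is the prior alone", {
  ds <- list(list(family = "binomial", y = numeric(0), n = numeric(0),
                  X = matrix(nrow = 0, ncol = 1,
                             dimnames = list(NULL, "log_NC")),
                  label = "empty"))
  pri <- hyper_priors()
  lp <- log_posterior(list(coef = list(c(0, 0))), ds, "glm", priors = pri)
  expect_equal(lp, 2 * stats::dnorm(0, 0, sqrt(1000), log = TRUE))
})

test_that("conjugate Gaussian toy recovers the closed-form posterior", {
  n <- 200
  ds <- toy_gaussian(n, mu = 1.3, seed = 99)
  ctl <- mcmc_control(n_chains = 2, n_warmup = 500, n_iter = 2000, seed = 4)
  ftt <- fit_model(ds, "glm", control = ctl)
  dm <- draw_matrix(ftt)[, "alpha_toy"]
  post_prec <- n + 0.001
  post_mean <- sum(ds[[1]]$y) / post_prec
  expect_equal(mean(dm), post_mean, tolerance = 4 / sqrt(post_prec * 4000))
  expect_equal(stats::var(dm), 1 / post_prec, tolerance = 0.15)
})

test_that("same seed and config reproduce identical draws", {
  cfg <- quick_scenario(seed = 63)
  dat <- simulate_dataset(cfg)
  spec <- model_spec("car", species = "invicta", datasets = "survey",
                     covariates = "log_NC")
  ctl <- mcmc_control(n_chains = 2, n_warmup = 100, n_iter = 100, seed = 9)
  f1 <- suppressWarnings(fit(dat, spec, control = ctl))
  f2 <- suppressWarnings(fit(dat, spec, control = ctl))
  expect_identical(f1$chains, f2$chains)
})

test_that("GLM posterior concentrates at the MLE for large surveys", {
  set.seed(71)
  N <- 40
  x <- stats::rnorm(N)
  eta <- -3 + 0.8 * x
  n <- rep(1000L, N)
  y <- stats::rbinom(N, n, stats::plogis(eta))
  ds <- list(list(family = "binomial", y = y, n = n,
                  X = cbind(log_NC = x), label = "survey_big"))
  ctl <- mcmc_control(n_chains = 2, n_warmup = 500, n_iter = 1500, seed = 10)
  ftb <- fit_model(ds, "glm", control = ctl)
  mle <- stats::glm(cbind(y, n - y) ~ x, family = stats::binomial())
  sm <- summary(ftb)
  expect_equal(sm$mean[sm$parameter == "alpha_survey_big"],
               unname(stats::coef(mle)[1]), tolerance = 0.02)
  expect_equal(sm$mean[sm$parameter == "beta_survey_big_log_NC"],
               unname(stats::coef(mle)[2]), tolerance = 0.03)
})

test_that("diagnostics flag shifted chains and pass iid draws", {
  set.seed(12)
  good <- matrix(stats::rnorm(4000), ncol = 4)
  expect_lt(split_rhat(good), 1.01)
  expect_equal(ess_basic(good), 4000, tolerance = 0.25)
  bad <- good + rep(c(0, 5, 0, 5), each = 1000)
  expect_gt(split_rhat(bad), 1.1)
})

test_that("run_diagnostics needs two chains and reports every scalar", {
  ds <- toy_gaussian(20)
  ctl1 <- mcmc_control(n_chains = 1, n_warmup = 100, n_iter = 100, seed = 2)
  f1 <- fit_model(ds, "glm", control = ctl1)
  expect_error(run_diagnostics(f1), "2 chains")
  ctl2 <- mcmc_control(n_chains = 3, n_warmup = 100, n_iter = 200, seed = 2)
  f2 <- suppressWarnings(fit_model(ds, "glm", control = ctl2))
  rep2 <- run_diagnostics(f2)
  expect_equal(nrow(rep2$table), length(f2$param_names))
  expect_true(all(is.finite(rep2$table$rhat)))
})

test_that("port-order permutation permutes theta and leaves hypers", {
  cfg <- quick_scenario(seed = 64)
  dat <- simulate_dataset(cfg)
  spec <- model_spec("car", species = "invicta", datasets = "survey",
                     covariates = "log_NC")
  ctl <- mcmc_control(n_chains = 2, n_warmup = 800, n_iter = 1200, seed = 14)
  f_orig <- suppressWarnings(fit(dat, spec, control = ctl))
  set.seed(15)
  perm <- sample(length(dat$roster))
  datp <- dat
  datp$roster <- dat$roster[perm]
  datp$n_surveys <- dat$n_surveys[perm]
  datp$det <- dat$det[perm, ]
  datp$po <- dat$po[perm, ]
  datp$covariates$nc <- dat$covariates$nc[perm, ]
  datp$covariates$log_nc <- dat$covariates$log_nc[perm, ]
  datp$covariates$mt <- dat$covariates$mt[perm]
  Wp <- dat$network$W[perm, perm]
  datp$network <- structure(
    list(ports = dat$network$ports[perm], W = Wp,
         alpha_scale = dat$network$alpha_scale, row_sums = rowSums(Wp)),
    class = "port_network")
  f_perm <- suppressWarnings(fit(datp, spec,
                                 control = mcmc_control(n_chains = 2,
                                                        n_warmup = 800,
                                                        n_iter = 1200,
                                                        seed = 16)))
  s_orig <- summary(f_orig); s_perm <- summary(f_perm)
  get <- function(s, p) s$mean[s$parameter == p]
  expect_lt(abs(get(s_orig, "lam") - get(s_perm, "lam")), 0.1)
  expect_lt(abs(get(s_orig, "beta_survey_invicta_log_NC") -
                  get(s_perm, "beta_survey_invicta_log_NC")), 0.1)
  # theta posterior means permute with the ports (within MC error)
  th_o <- s_orig$mean[grep("^theta", s_orig$parameter)]
  th_p <- s_perm$mean[grep("^theta", s_perm$parameter)]
  expect_lt(max(abs(th_p - th_o[perm])), 0.35)
})
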