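# hand-built degenerate posterior: every draw identical
degenerate_fit <- function() {
  set.seed(41)
  N <- 10
  x <- stats::rnorm(N)
  n <- rep(15L, N)
  y <- stats::rbinom(N, n, 0.3)
  co <- c(-0.8, 0.4)
  row <- c(alpha_s = co[1], beta_s_log_NC = co[2])
  draws <- matrix(rep(row, each = 50), nrow = 50,
                  dimnames = list(NULL, c("alpha_s", "beta_s_log_NC")))
  structure(
    list(chains = list(draws, draws),
         param_names = colnames(draws), model_type = "glm",
         datasets = list(list(family = "binomial", y = y, n = n,
                              X = cbind(log_NC = x), label = "s")),
         network = NULL, N = N, labels = "s",
         control = mcmc_control(n_chains = 2, n_warmup = 0, n_iter = 50,
                                seed = 1)),
    class = "posterior_samples")
}

test_that("degenerate posterior gives p_d = 0 and WAIC at the point mass", {
  ft <- degenerate_fit()
  sc <- compute_dic(ft)
  expect_equal(sc$p_d, 0, tolerance = 1e-10)
  d <- ft$datasets[[1]]
  eta <- -0.8 + 0.4 * d$X[, 1]
  dev_hat <- -2 * sum(stats::dbinom(d$y, d$n, stats::plogis(eta), log = TRUE))
  expect_equal(sc$dic, dev_hat, tolerance = 1e-10)
  wc <- compute_waic(ft)
  expect_equal(wc$waic, dev_hat, tolerance = 1e-10)
  expect_equal(wc$p_waic, 0, tolerance = 1e-12)
})

test_that("conjugate Gaussian toy p_d matches the shrinkage factor", {
  n <- 150
  ds <- toy_gaussian(n, mu = 0.7, seed = 55)
  ctl <- mcmc_control(n_chains = 2, n_warmup = 500, n_iter = 2500, seed = 8)
  ftt <- fit_model(ds, "glm", control = ctl)
  sc <- compute_dic(ftt)
  expect_equal(sc$p_d, n / (n + 0.001), tolerance = 0.08)
})

test_that("local DIC components sum to the total exactly", {
  cfg <- quick_scenario(seed = 81)
  dat <- simulate_dataset(cfg)
  spec <- model_spec("mcar_dt", species = "invicta",
                     datasets = c("survey", "po"), covariates = "log_NC")
  ctl <- mcmc_control(n_chains = 2, n_warmup = 400, n_iter = 400, seed = 18)
  ft <- suppressWarnings(fit(dat, spec, control = ctl))
  sc <- compute_dic(ft)
  expect_equal(sum(sc$local$dic), sc$dic, tolerance = 1e-9)
  expect_equal(sum(sc$local$p_d), sc$p_d, tolerance = 1e-9)
  wc <- compute_waic(ft)
  expect_equal(sum(wc$local$waic), wc$waic, tolerance = 1e-9)
})

test_that("DIC is invariant to reordering draws and data points", {
  cfg <- quick_scenario(seed = 82)
  dat <- simulate_dataset(cfg)
  spec <- model_spec("glm", species = "invicta", datasets = "survey",
                     covariates = "log_NC")
  ctl <- mcmc_control(n_chains = 2, n_warmup = 300, n_iter = 300, seed = 19)
  ft <- suppressWarnings(fit(dat, spec, control = ctl))
  base <- compute_dic(ft)$dic
  set.seed(20)
  ft_shuf <- ft
  ft_shuf$chains <- lapply(ft$chains, function(ch) ch[sample(nrow(ch)), ])
  expect_equal(compute_dic(ft_shuf)$dic, base, tolerance = 1e-9)
  perm <- sample(ft$N)
  ft_perm <- ft
  d <- ft$datasets[[1]]
  ft_perm$datasets[[1]]$y <- d$y[perm]
  ft_perm$datasets[[1]]$n <- d$n[perm]
  ft_perm$datasets[[1]]$X <- d$X[perm, , drop = FALSE]
  # draws refer to ports only through theta; a GLM has none, so the
  # likelihood is exchangeable in the data points
  expect_equal(compute_dic(ft_perm)$dic, base, tolerance = 1e-9)
})

test_that("WAIC and DIC rank nested GLMs identically under a strong effect", {
  set.seed(83)
  N <- 65
  x <- stats::rnorm(N)
  n <- rep(15L, N)
  y <- stats::rbinom(N, n, stats::plogis(-2 + 2 * x))
  ds_full <- list(list(family = "binomial", y = y, n = n,
                       X = cbind(log_NC = x), label = "s"))
  ds_null <- list(list(family = "binomial", y = y, n = n,
                       X = matrix(nrow = N, ncol = 0), label = "s"))
  ctl <- mcmc_control(n_chains = 2, n_warmup = 400, n_iter = 800, seed = 21)
  f_full <- fit_model(ds_full, "glm", control = ctl)
  f_null <- fit_model(ds_null, "glm", control = ctl)
  dic_diff <- compute_dic(f_full)$dic - compute_dic(f_null)$dic
  waic_diff <- compute_waic(f_full)$waic - compute_waic(f_null)$waic
  expect_lt(dic_diff, 0)
  expect_lt(waic_diff, 0)
  expect_equal(sign(dic_diff), sign(waic_diff))
})

test_that("the retention rule is strict at a DIC increase of exactly 2", {
  expect_false(covariate_retained(100, 102))
  expect_true(covariate_retained(100, 102.0001))
  expect_false(covariate_retained(100, 99))
})

test_that("stepwise selection drops a null covariate and keeps a real one", {
  cfg <- quick_scenario(seed = 84, beta_nc = 1, beta_mt = 0, latent = FALSE)
  dat <- simulate_dataset(cfg)
  spec <- model_spec("glm", species = "invicta", datasets = "survey",
                     covariates = c("log_NC", "MT"))
  ctl <- mcmc_control(n_chains = 2, n_warmup = 400, n_iter = 800, seed = 22)
  sel <- stepwise_select(dat, spec, control = ctl)
  expect_true("log_NC" %in% sel$spec$covariates)
  expect_equal(nrow(sel$trace), 3L)
  expect_true(all(c("reference", "covariate kept", "covariate dropped")
                  %in% sel$trace$decision) ||
                all(sel$trace$decision[2:3] %in%
                      c("covariate kept", "covariate dropped")))
})

test_that("comparison table carries local and total scores per model", {
  cfg <- quick_scenario(seed = 85)
  dat <- simulate_dataset(cfg)
  ctl <- mcmc_control(n_chains = 2, n_warmup = 300, n_iter = 300, seed = 23)
  f1 <- suppressWarnings(fit(dat, model_spec("glm", species = "invicta",
                                             datasets = "survey",
                                             covariates = "log_NC"),
                             control = ctl))
  f2 <- suppressWarnings(fit(dat, model_spec("mcar_dt", species = "invicta",
                                             datasets = c("survey", "po"),
                                             covariates = "log_NC"),
                             control = ctl))
  tab <- comparison_table(list(glm = f1, mcar_dt = f2))
  expect_equal(nrow(tab), 3L)  # 1 glm dataset + 2 joint datasets
  expect_true(all(c("local_dic", "total_dic", "local_waic", "total_waic")
                  %in% names(tab)))
  agg <- tapply(tab$local_dic, tab$model, sum)
  tot <- tapply(tab$total_dic, tab$model, unique)
  expect_equal(as.numeric(agg[names(tot)]), as.numeric(tot),
               tolerance = 1e-9)
})
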