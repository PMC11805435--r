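// Adaptive Metropolis-within-Gibbs sampler for GLM / Leroux CAR / MCAR
// introduction-risk models. Latent effects are updated site by site
// against their Gaussian full conditional (prior) and the observation
// likelihood; precision parameters use exact conjugate draws (gamma for
// the univariate model, Wishart for the cross-dataset precision); the
// dependence parameter lambda moves by random walk on the logit scale
// with the log-determinant evaluated from the precomputed eigenvalues
// of diag(W1) - W. All randomness comes from R's RNG so a set.seed()
// in R makes chains bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// families: 0 binomial, 1 poisson, 2 gaussian (known sigma)
static inline double site_loglik(int family, double y, double n,
                                 double eta, double sigma) {
  switch (family) {
  case 0: {
    // y*eta - n*log(1+exp(eta)), stable for large |eta|
    double lse = (eta > 35.0) ? eta : std::log1p(std::exp(eta));
    if (eta < -35.0) lse = 0.0;
    return y * eta - n * lse;
  }
  case 1:
    return y * eta - std::exp(eta);
  default: {
    double r = (y - eta) / sigma;
    return -0.5 * r * r;
  }
  }
}

static inline double vec_loglik(int family, const arma::vec& y,
                                const arma::vec& n, const arma::vec& eta,
                                double sigma) {
  double s = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i)
    s += site_loglik(family, y[i], n[i], eta[i], sigma);
  return s;
}

static inline double logdet_R(double lam, const arma::vec& meig) {
  double s = 0.0;
  for (arma::uword i = 0; i < meig.n_elem; ++i)
    s += std::log(1.0 - lam + lam * meig[i]);
  return s;
}

// Bartlett decomposition draw from Wishart(df, Scale) using R's RNG
static arma::mat rwishart(double df, const arma::mat& scale) {
  const arma::uword p = scale.n_rows;
  arma::mat L = arma::chol(scale, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (arma::uword i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// [[Rcpp::export(name = ".run_mcmc_chain")]]
List run_mcmc_chain(List datasets, int model_type, arma::mat W,
                    arma::vec meig, List priors, int n_warmup,
                    int n_iter, int thin, List init) {
  const int nd = datasets.size();
  const bool has_theta = model_type != 0;

  // unpack datasets
  std::vector<arma::vec> y(nd), ntr(nd), eta(nd), theta(nd);
  std::vector<arma::mat> X(nd);
  std::vector<int> family(nd), p(nd);
  std::vector<double> sigma(nd);
  int N = 0;
  for (int j = 0; j < nd; ++j) {
    List dj = datasets[j];
    y[j] = as<arma::vec>(dj["y"]);
    X[j] = as<arma::mat>(dj["X"]);
    family[j] = as<int>(dj["family_code"]);
    sigma[j] = dj.containsElementNamed("sigma") ? as<double>(dj["sigma"]) : 1.0;
    if (dj.containsElementNamed("n") && !Rf_isNull(dj["n"]))
      ntr[j] = as<arma::vec>(dj["n"]);
    else
      ntr[j] = arma::vec(y[j].n_elem, arma::fill::ones);
    p[j] = X[j].n_cols;
    N = y[j].n_elem;
  }

  // priors
  const double beta_prec = as<double>(priors["beta_prec"]);
  const double tau_shape = as<double>(priors["tau_shape"]);
  const double tau_rate = as<double>(priors["tau_rate"]);
  const double wish_df = as<double>(priors["wishart_df"]);
  arma::mat wish_scale_inv(1, 1, arma::fill::eye);
  if (nd == 2)
    wish_scale_inv = arma::inv_sympd(as<arma::mat>(priors["wishart_scale"]));

  // state
  std::vector<arma::vec> coef(nd);
  for (int j = 0; j < nd; ++j) {
    coef[j] = as<arma::vec>(as<List>(init["coef"])[j]);
    theta[j] = arma::vec(N, arma::fill::zeros);
    eta[j] = X[j] * coef[j] + theta[j];
  }
  double lam = has_theta ? as<double>(init["lam"]) : 0.0;
  arma::mat Lambda(nd, nd, arma::fill::eye);  // tau for CAR lives in (0,0)
  if (has_theta && init.containsElementNamed("Lambda"))
    Lambda = as<arma::mat>(init["Lambda"]);

  arma::vec rs = has_theta ? arma::vec(arma::sum(W, 1)) : arma::vec();
  arma::mat R;  // Leroux structure (1-lam)I + lam(diag(rs)-W)
  if (has_theta) {
    R = -lam * W;
    R.diag() = (1.0 - lam) + lam * rs;
  }

  // adaptive proposal sds
  std::vector<arma::vec> coef_sd(nd), coef_acc(nd);
  for (int j = 0; j < nd; ++j) {
    coef_sd[j] = arma::vec(p[j], arma::fill::value(0.1));
    coef_acc[j] = arma::vec(p[j], arma::fill::zeros);
  }
  std::vector<arma::vec> th_sd(nd), th_acc(nd);
  for (int j = 0; j < nd; ++j) {
    th_sd[j] = arma::vec(N, arma::fill::value(0.5));
    th_acc[j] = arma::vec(N, arma::fill::zeros);
  }
  double lam_sd = 1.0, lam_acc = 0.0;
  int batch = 0, batch_len = 50;

  // output layout: coefs | theta | hyper
  int n_hyper = has_theta ? (nd == 1 ? 2 : 4) : 0;  // tau,lam | tau1,tau2,rho,lam
  int npar = 0;
  for (int j = 0; j < nd; ++j) npar += p[j];
  if (has_theta) npar += nd * N;
  npar += n_hyper;
  const int n_keep = n_iter / thin;
  arma::mat out(n_keep, npar);

  double lam_acc_total = 0.0, th_acc_total = 0.0;
  long th_try_total = 0, lam_try_total = 0;

  const int total_iter = n_warmup + n_iter;
  for (int it = 0; it < total_iter; ++it) {
    const bool warm = it < n_warmup;

    // --- regression coefficients, componentwise RW ---
    for (int j = 0; j < nd; ++j) {
      for (int c = 0; c < p[j]; ++c) {
        double cur = coef[j][c];
        double prop = cur + coef_sd[j][c] * norm_rand();
        arma::vec eta_prop = eta[j] + X[j].col(c) * (prop - cur);
        double d = vec_loglik(family[j], y[j], ntr[j], eta_prop, sigma[j]) -
                   vec_loglik(family[j], y[j], ntr[j], eta[j], sigma[j]) +
                   0.5 * beta_prec * (cur * cur - prop * prop);
        if (std::log(unif_rand()) < d) {
          coef[j][c] = prop;
          eta[j] = eta_prop;
          if (warm) coef_acc[j][c] += 1.0;
        }
      }
    }

    if (has_theta) {
      // --- latent effects, single-site RW against GMRF conditional ---
      for (int j = 0; j < nd; ++j) {
        int l = 1 - j;  // other dataset (unused when nd == 1)
        for (int i = 0; i < N; ++i) {
          double Rii = R(i, i);
          double own = arma::dot(R.row(i), theta[j]) - Rii * theta[j][i];
          double b = Lambda(j, j) * own;
          if (nd == 2) b += Lambda(j, l) * arma::dot(R.row(i), theta[l]);
          double prec = Lambda(j, j) * Rii;
          double cmean = -b / prec;
          double cur = theta[j][i];
          double prop = cur + th_sd[j][i] * norm_rand();
          double d =
              site_loglik(family[j], y[j][i], ntr[j][i],
                          eta[j][i] + (prop - cur), sigma[j]) -
              site_loglik(family[j], y[j][i], ntr[j][i], eta[j][i], sigma[j]) -
              0.5 * prec * ((prop - cmean) * (prop - cmean) -
                            (cur - cmean) * (cur - cmean));
          ++th_try_total;
          if (std::log(unif_rand()) < d) {
            theta[j][i] = prop;
            eta[j][i] += prop - cur;
            th_acc_total += 1.0;
            if (warm) th_acc[j][i] += 1.0;
          }
        }
      }

      // quadratic forms u = theta_j.theta_l, m = theta_j' M theta_l
      // with M = diag(rs) - W, so theta' R theta = (1-lam)u + lam*m
      arma::mat u(nd, nd), m(nd, nd);
      std::vector<arma::vec> Mth(nd);
      for (int j = 0; j < nd; ++j) Mth[j] = rs % theta[j] - W * theta[j];
      for (int j = 0; j < nd; ++j)
        for (int l2 = 0; l2 < nd; ++l2) {
          u(j, l2) = arma::dot(theta[j], theta[l2]);
          m(j, l2) = arma::dot(theta[j], Mth[l2]);
        }

      // --- precision: conjugate Gibbs ---
      if (nd == 1) {
        double q = (1.0 - lam) * u(0, 0) + lam * m(0, 0);
        double shape = tau_shape + 0.5 * N;
        double rate = tau_rate + 0.5 * q;
        Lambda(0, 0) = R::rgamma(shape, 1.0 / rate);
      } else {
        arma::mat S = (1.0 - lam) * u + lam * m;
        arma::mat post_scale = arma::inv_sympd(wish_scale_inv + S);
        post_scale = 0.5 * (post_scale + post_scale.t());
        Lambda = rwishart(wish_df + N, post_scale);
      }

      // --- lambda: logit-scale RW ---
      {
        double cur = lam;
        double lcur = std::log(cur / (1.0 - cur));
        double lprop = lcur + lam_sd * norm_rand();
        double prop = 1.0 / (1.0 + std::exp(-lprop));
        // guard against the lam = 1 boundary (improper ICAR limit)
        if (prop < 1.0 - 1e-12) {
          double qc = 0.0, qp = 0.0;
          for (int j = 0; j < nd; ++j)
            for (int l2 = 0; l2 < nd; ++l2) {
              qc += Lambda(j, l2) * ((1.0 - cur) * u(j, l2) + cur * m(j, l2));
              qp += Lambda(j, l2) * ((1.0 - prop) * u(j, l2) + prop * m(j, l2));
            }
          double half_nd = 0.5 * (double)nd;
          double d = half_nd * (logdet_R(prop, meig) - logdet_R(cur, meig)) -
                     0.5 * (qp - qc) +
                     std::log(prop * (1.0 - prop)) -
                     std::log(cur * (1.0 - cur));
          ++lam_try_total;
          if (std::log(unif_rand()) < d) {
            lam = prop;
            lam_acc_total += 1.0;
            if (warm) lam_acc += 1.0;
            R = -lam * W;
            R.diag() = (1.0 - lam) + lam * rs;
          }
        } else {
          ++lam_try_total;
        }
      }
    }

    // --- adaptation during warmup ---
    if (warm && ((it + 1) % batch_len == 0)) {
      ++batch;
      double delta = std::min(0.05, 1.0 / std::sqrt((double)batch));
      for (int j = 0; j < nd; ++j) {
        for (int c = 0; c < p[j]; ++c) {
          double r = coef_acc[j][c] / batch_len;
          coef_sd[j][c] *= std::exp(r > 0.44 ? delta : -delta);
          coef_acc[j][c] = 0.0;
        }
        if (has_theta)
          for (int i = 0; i < N; ++i) {
            double r = th_acc[j][i] / batch_len;
            th_sd[j][i] *= std::exp(r > 0.44 ? delta : -delta);
            th_acc[j][i] = 0.0;
          }
      }
      if (has_theta) {
        double r = lam_acc / batch_len;
        lam_sd *= std::exp(r > 0.44 ? delta : -delta);
        lam_sd = std::min(lam_sd, 4.0);
        lam_acc = 0.0;
      }
    }

    // --- record ---
    if (!warm && ((it - n_warmup + 1) % thin == 0)) {
      int row = (it - n_warmup) / thin;
      int col = 0;
      for (int j = 0; j < nd; ++j)
        for (int c = 0; c < p[j]; ++c) out(row, col++) = coef[j][c];
      if (has_theta) {
        for (int j = 0; j < nd; ++j)
          for (int i = 0; i < N; ++i) out(row, col++) = theta[j][i];
        if (nd == 1) {
          out(row, col++) = Lambda(0, 0);
          out(row, col++) = lam;
        } else {
          arma::mat V = arma::inv_sympd(Lambda);
          out(row, col++) = 1.0 / V(0, 0);
          out(row, col++) = 1.0 / V(1, 1);
          out(row, col++) = V(0, 1) / std::sqrt(V(0, 0) * V(1, 1));
          out(row, col++) = lam;
        }
      }
    }
  }

  return List::create(
      _["draws"] = out,
      _["accept_theta"] =
          th_try_total > 0 ? th_acc_total / (double)th_try_total : NA_REAL,
      _["accept_lam"] =
          lam_try_total > 0 ? lam_acc_total / (double)lam_try_total : NA_REAL);
}
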