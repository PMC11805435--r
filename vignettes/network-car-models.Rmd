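---
title: "Network CAR models for introduction risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network CAR models for introduction risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Invasive species arrive at ports inside cargo containers. In the
introduction stage the data are thin: a designed port survey gives a
handful of detections out of a known number of trials per port, and an
opportunistic stream of presence-only records gives event counts with
unknown effort. Classical spatial smoothing is of little help because
human-mediated introduction does not correlate with geographical
distance — a container unloaded at one port may have transited several
others far away. What does connect ports is the container-logistics
network itself. `flowcar` therefore replaces the usual geographic
adjacency with a flow-weighted network and shares information between
ports, between data types, and between species through conditional
autoregressive (CAR) priors defined on that network.

## The weight matrix

From an edge list of annual container volumes the package builds a
symmetric flow matrix (volumes in the two directions are summed by
default; a `max` rule is available since the data source may report
either convention), zeroes the diagonal, and rescales the whole matrix
by `alpha_scale = 1/max` so the largest weight is exactly 1. Scaling
matters: a CAR prior is usually written for a binary adjacency matrix,
and the scale of W changes the meaning of the dependence parameter. The
max-1 rescaling keeps the precision matrix positive definite (it is a
positive multiple), which the package verifies property-style on random
networks. Ports with no recorded flows are allowed; their conditional
prior degenerates gracefully to an independent normal, and construction
warns so the user knows the network is not connected.

## Latent fields

The univariate prior on the port effects $\theta$ is the Leroux CAR,

$$\theta \sim N\!\left(0,\; \tau^{-1}\left[(1-\lambda)I +
\lambda\{\mathrm{diag}(W\mathbf{1}) - W\}\right]^{-1}\right),$$

whose conditional form at port $i$ has mean
$\lambda \sum_{i'} w_{ii'}\theta_{i'} / (\lambda \sum_{i'} w_{ii'} + 1 -
\lambda)$ and variance $\tau^{-1}/(\lambda \sum_{i'} w_{ii'} + 1 -
\lambda)$: $\lambda = 0$ is independence, $\lambda \to 1$ the intrinsic
CAR. The package restricts $\lambda \in [0, 1)$. At $\lambda = 1$
exactly, the structure matrix of a connected graph is singular and the
joint density improper; since propriety is the reason to use the Leroux
form at all, the boundary is excluded, and the sampler's logit-scale
random walk never reaches it.

Two datasets are integrated by stacking their fields,
$\Theta = [\theta_1^\top, \theta_2^\top]^\top$, with the multivariate
(MCAR) prior $\Theta \sim N(0, \Lambda^{-1} \otimes R(\lambda)^{-1})$,
where $R(\lambda)$ is the shared Leroux structure and

$$\Lambda^{-1} = \begin{pmatrix} \tau_1^{-1} & \rho/\sqrt{\tau_1\tau_2}
\\ \rho/\sqrt{\tau_1\tau_2} & \tau_2^{-1} \end{pmatrix}.$$

The off-diagonal is written with the square root deliberately: that is
the only parameterization in which $\rho$ is the correlation
coefficient between the two fields and $\Lambda^{-1}$ a valid
covariance. A single $\lambda$ is shared by both components — the
Kronecker structure implies one structure block. The same machinery
serves both integration schemes: survey plus presence-only data of one
species (`mcar_dt`), and the survey data of two species (`mcar_sp`).

## Observation models

Survey detections are binomial,
$Y_{i1} \sim \mathrm{Bin}(n_{i,\mathrm{survey}}, p_i)$ with
$\mathrm{logit}(p_i) = \alpha_1 + \beta_{1,1}\log(\mathrm{NC}_i + 1) +
\beta_{1,2}\,\mathrm{MT}_i + \theta_{i1}$, and presence-only records are
Poisson, $Y_{i2} \sim \mathrm{Pois}(\lambda_i)$ with the analogous log
link. NC is the annual count of containers imported from source regions
where the species is established; it enters on the log scale under the
propagule-pressure view that risk grows sub-linearly in volume. The
pseudocount 1 keeps zero-volume ports finite and preserves ordering; it
is configurable because the choice is a convention, not a fact about the
data. MT, the annual minimum temperature, enters untransformed.
Covariates are not standardized by default so coefficients stay on
interpretable units; a z-scoring flag exists for conditioning. The
relative size of $p_i$ across ports is the quantity of applied interest
— the relative introduction risk — and `rank_ports()` reports its
posterior mean, 95% interval and rank per port.

## Priors and inference

Hyperpriors are weakly informative and fixed by default: fixed effects
$N(0, 1/0.001)$; $\tau \sim \mathrm{Gamma}(\text{shape } 1,
\text{scale } 100)$; $\lambda \sim U(0,1)$; and for joint models
$\Lambda \sim \mathrm{Wishart}(4, I_2)$ in the scale convention, so the
prior mean of $\Lambda$ is $4I$.

The posterior is sampled by adaptive Metropolis-within-Gibbs,
implemented in C++:

* **Fixed effects** move one at a time by random walk. Covariates are
  centered internally before sampling and the intercept draws shifted
  back afterwards — an exact reparameterization that removes the strong
  intercept–slope correlation and was the single largest mixing
  improvement in development.
* **Latent effects** update site by site against the product of the
  observation likelihood at that port and the Gaussian full conditional
  implied by the joint precision $\Lambda \otimes R(\lambda)$ (for the
  univariate model, $\tau R(\lambda)$).
* **Precisions are Gibbs steps.** Given $\Theta$ and $\lambda$, the
  gamma prior on $\tau$ and the Wishart prior on $\Lambda$ are exactly
  conjugate (the sufficient statistic is $S_{jl} = \theta_j^\top
  R(\lambda)\, \theta_l$), so both are drawn from their full
  conditionals. This was preferred over Metropolis moves on transformed
  scales: the draws are exact, tuning-free, and mix better.
* **$\lambda$** moves by random walk on the logit scale. The
  log-determinant of $R(\lambda)$ is evaluated in $O(N)$ from the
  precomputed eigenvalues of $\mathrm{diag}(W\mathbf{1}) - W$, since
  $\log|R(\lambda)| = \sum_m \log(1 - \lambda + \lambda e_m)$.

Proposal scales adapt in batches of 50 during warmup toward a 44%
acceptance rate with diminishing adaptation, then freeze. All
randomness flows through R's RNG, so a seed in `mcmc_control()` makes
chains bit-reproducible; chain seeds are derived deterministically from
the run seed. Defaults are 4 chains of 2,000 warmup + 2,000 retained
draws; convergence is summarized by split R-hat and effective sample
size for every scalar, with a fit-level flag (threshold 1.05 by
default) raised as a warning, never silently. The R-side
`log_posterior()` is a straight-line reimplementation of the target
density and serves as the sampler's audit point in the tests, alongside
a conjugate Gaussian toy with a closed-form posterior.

## Model comparison

DIC is computed as $\bar D + p_D$ with $p_D = \bar D - D(\hat\mu)$,
plugging in the posterior mean of the likelihood-level parameters
($p_i$, $\lambda_i$) — the convention used with latent Gaussian models;
plugging in the posterior-mean linear predictor instead is available by
flag, because the two conventions can differ noticeably when the latent
field is weakly identified. For joint models the deviance separates by
dataset, and each dataset's $\bar D_j + p_{D,j}$ is reported as its
local DIC; the locals sum to the total exactly by construction, which
is how a joint fit can be compared dataset-by-dataset against the
corresponding separate models. WAIC is computed from the pointwise
posterior likelihood with the variance penalty and reported in the same
deviance units as a cross-check.

Covariate selection is stepwise against the full model: a covariate is
retained only if removing it raises the DIC by strictly more than 2 (a
rise of exactly 2 drops it). Only single-covariate reductions are
compared; dropping both covariates at once is not considered.

## The synthetic generator

No simulation study accompanied the motivating analysis, so the
generator's distributions are the package's own choices, fixed once and
fully seed-controlled:

* **Network**: hub-and-spoke with 4 hubs split over two clusters, the
  topology observed in national container systems. Hub–hub volumes are
  large log-normals, every spoke attaches to its cluster's hubs with
  log-normal volumes, spoke–spoke edges appear with probability 0.15
  within a cluster and 0.01 across clusters. The resulting weight
  matrix is sparse (well over half the off-diagonal entries are zero)
  and the two clusters are rarely connected except through hubs.
* **Covariates**: log import volumes are Gaussian around a linear
  function of the port's standardized weighted degree (large ports
  import more); temperature follows a linear north–south gradient in
  port order with sd-1 noise (zero noise gives an exactly linear
  gradient, used as a degenerate test case).
* **Observations**: 65 ports, 13–20 surveys each, and true parameters
  $\beta_{NC} = 0.5$, $\beta_{MT} = 0$, $\lambda = 0.5$,
  $\tau_1 = \tau_2 = 2$, $\rho = 0.5$. The intercepts (−7.2 survey,
  −3.5 presence-only) were calibrated once so that the replicate-mean
  detection frequency is about 2% per survey and the total
  presence-only count about 110–120 — the magnitudes the motivating
  survey actually produced — and are not revisited.

What the generator does **not** emulate: unequal survey effort between
ports beyond the trial count, seasonality in either data stream,
transshipment through ports outside the roster, cross-species
correlation in the latent fields (species are simulated
independently), and any resemblance between the synthetic flow volumes
and a real country's statistics. Passing recovery tests therefore show
that the estimator works when its assumptions hold at the study's
scale; they do not validate those assumptions for real data.

A separate deterministic object, `synthetic_study_data()`, encodes the
published marginal counts of the motivating survey (975 trials, 50
detections, 11 positive ports per species, 115 presence-only records,
the 8-of-19 maximum) in an otherwise invented table. It exists so the
input pipeline and the count identities can be exercised without any
real port-level data; it is synthetic and labelled as such.

## Validation scale and numerical choices

The test-suite experiments run at deliberately chosen sizes: the GMRF
conditional oracle uses 100 random networks of up to 8 ports compared
to dense-matrix conditionals at 10 significant digits; the Kronecker
identity is checked densely up to 6 ports; parameter recovery uses 50
replicates at the full 65-port scale with 2 chains of 1,000 + 1,000
draws (coverage of $\beta_{NC}$ lands in the high 0.9s, and the
posterior mean of $\rho$ is positive under a $\rho = 0.5$ truth and
near zero under independence — $\rho$ is weakly identified at 65 ports
and shrinks toward zero, the same behaviour the motivating analysis
reported); stepwise selection is replicated 20 times; the joint-versus-
separate DIC comparison 20 times. These sizes give Monte-Carlo error
comfortably below the decision margins being tested.

Numerically: log-determinants and GMRF draws go through dense Cholesky
factorizations, stable and fast to a few hundred ports — no sparse
machinery is warranted at this scale; the binomial log-likelihood is
written with `log1p` guards so saturated predictors do not overflow;
ties in the risk ranking break by roster order; an MCMC fit whose
R-hat exceeds the threshold is returned flagged rather than failing, so
selection procedures can abort with their partial trace intact.

## Limitations

The inference contract is the exact posterior via MCMC; the original
analysis used INLA, whose internal Wishart conventions differ across
versions, so exact prior equivalence with any particular INLA run is
not claimed. Only pairwise integration is supported (the Kronecker
cross-precision is 2×2). The intrinsic CAR limit, zero-inflated or
negative-binomial observation variants, trap-type detection submodels,
and graph-theoretic risk metrics are all out of scope; the network
enters the model only through W.
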