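Package: flowcar
Title: Conditional Autoregressive Models on Logistics Networks for
    Species Introduction Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hierarchical Bayesian estimation of invasive-species
    introduction risk at ports, where dependence between ports is carried
    by a container-logistics flow network rather than geographical
    distance. Provides the Leroux conditional autoregressive (CAR) prior
    and its multivariate extension (MCAR) with a Kronecker-structured
    precision over a symmetric, max-scaled flow weight matrix; binomial
    survey and Poisson presence-only observation models with log-volume
    and temperature covariates; Metropolis-within-Gibbs posterior
    sampling with conjugate updates for precision parameters; DIC and
    WAIC model comparison including per-dataset local DIC; stepwise
    covariate selection; a synthetic hub-and-spoke data generator for
    end-to-end validation; and CSV/YAML input-output utilities with a
    scripted pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
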