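# flowcar

Bayesian estimation of invasive-species introduction risk at ports,
with dependence between ports carried by the container-logistics
network instead of geographical distance.

## The problem and who this is for

In the introduction stage of a biological invasion the data are sparse:
a designed port survey yields a few detections out of a known number of
trials per port, and opportunistic presence-only records give event
counts with unknown effort. Since container-borne introduction does not
follow geographic proximity, conventional spatial models have nothing
to smooth over. `flowcar` is for biosecurity analysts and quantitative
ecologists who want to rank ports by relative introduction risk while
borrowing strength along the logistics network — between connected
ports, between data types (survey + presence-only), and between species
with a shared introduction pathway.

## The model

Let `W` be the symmetric container-flow matrix between `N` ports,
rescaled so its largest entry is 1, with zero diagonal. Port effects
follow the Leroux CAR prior

    theta ~ N(0, tau^-1 [(1 - lambda) I + lambda {diag(W 1) - W}]^-1),

interpolating between independence (`lambda = 0`) and the intrinsic CAR
(`lambda -> 1`). Two datasets are integrated by stacking their fields
with the multivariate (MCAR) prior

    Theta ~ N(0, Lambda^-1 (x) R(lambda)^-1),
    Lambda^-1 = [ 1/tau1              rho/sqrt(tau1 tau2) ]
                [ rho/sqrt(tau1 tau2) 1/tau2              ]

where `(x)` is the Kronecker product and `rho` the correlation between
the two fields. Observations are binomial for surveys —
`Y_i1 ~ Bin(n_i, p_i)`, `logit(p_i) = alpha_1 + beta_1 log(NC_i + 1) +
beta_2 MT_i + theta_i1` — and Poisson for presence-only records with
the analogous log link. `NC` is the imported-container count from
source regions, `MT` the annual minimum temperature. Models (GLM,
univariate CAR, MCAR over data types, MCAR over species) are fitted by
adaptive Metropolis-within-Gibbs with conjugate precision updates, and
compared by DIC (with per-dataset local components) and WAIC; covariate
selection is stepwise with a strict DIC-increase-of-2 rule.

## Worked example

Simulate a 65-port hub-and-spoke scenario at the package's default
study scale and fit the joint survey + presence-only model for one
species:

```r
library(flowcar)
dat <- simulate_dataset(scenario_config(seed = 42))
spec <- model_spec("mcar_dt", species = "invicta",
                   datasets = c("survey", "po"), covariates = "log_NC")
ft <- fit(dat, spec, control = mcmc_control(n_chains = 4, n_warmup = 2000,
                                            n_iter = 2000, seed = 1))
sm <- summary(ft)
sm[!grepl("theta", sm$parameter), ]
```

```
                  parameter  mean   sd    q2.5 q97.5
       alpha_survey_invicta -8.20 1.14 -10.781 -6.25
 beta_survey_invicta_log_NC  0.66 0.16   0.369  0.99
           alpha_po_invicta -3.22 0.71  -4.824 -1.94
     beta_po_invicta_log_NC  0.47 0.10   0.276  0.69
                       tau1  2.33 1.98   0.386  8.09
                       tau2  3.32 1.82   1.006  8.05
                        rho -0.03 0.38  -0.713  0.72
                        lam  0.50 0.25   0.029  0.91
```

The true generative values were `beta = 0.5`, `lambda = 0.5`,
`rho = 0.5`: both container-volume coefficients are recovered with
intervals containing the truth, `lambda` centers near 0.5, and `rho` —
weakly identified from 65 ports, as expected — has a wide interval
covering zero. This fit raises a convergence warning (max split R-hat
1.067 against the strict 1.05 default): the slow scalar is a latent
effect at a near-uninformative port, and the fit is returned flagged
rather than hidden.

```r
compute_dic(ft)
#> DIC: 228.306  (p_D = 30.83 )
#> local components:
#>         dataset     dbar     dhat     p_d      dic
#>  survey_invicta  73.1034  60.0863 13.0171  86.1205
#>      po_invicta 124.3742 106.5632 17.8110 142.1851

head(rank_ports(ft), 3)
#>   port       mean        q2.5     q97.5 rank
#> 1  P01 0.32477594 0.131154532 0.5680885    1
#> 2  P03 0.10420341 0.025924686 0.2285402    2
#> 3  P02 0.08804281 0.012188923 0.2085779    3
```

The local DIC rows let a joint model be compared dataset-by-dataset
against separate fits; `rank_ports()` gives the port priority list
(here the hubs P01–P04 and a high-volume spoke lead, as built into the
scenario). A YAML-driven pipeline (`cli_run("config.yml")`, or the
`inst/exec/flowcar` wrapper) runs read → aggregate → fit → score →
report and writes draws, comparison table, risk ranking and a JSON
manifest.

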