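# eventfuse

Integrated Bayesian event-time survival analysis for studies in which some
individuals have known (interval-censored) fates and the rest are only
detected imperfectly.

## The problem

Continuous-time survival methods need death times.  In wildlife telemetry
studies only part of the sample delivers them: radio-collared animals are
checked repeatedly, so their death times are known to the interval between
the last check alive and the first check dead, while animals carrying only
a mark — or a failed transmitter — are resighted with probability below one
and their deaths are never observed.  `eventfuse` is for analysts of such
mixed samples (telemetry studies, chick/nest survival monitoring, any
marked population with partial follow-up) who want hazard-scale inference
without discarding the unknown-fate animals.

## The model

A piecewise-constant hazard `h(u)` (per day), optionally scaled by
log-linear proportional-hazards covariates `exp(x'β)`, is shared by two
likelihood components:

* **Known fate** (entry `e`, last alive `r`, first dead `s`):
  `S(e, r) · [1 − S(r, s)]`, or `S(e, r)` if right-censored, where
  `S(a, b) = exp(−∫ₐᵇ h(u) du)`.  Staggered entry is handled by
  conditioning on survival to `e` (left truncation).
* **Unknown fate** (entry `e`, `nn` sightings, last seen at `t*`, surveys
  at times `u₁ < … < u_m` after `t*`):
  `S(e, t*) · p^nn (1−p)^(n_avail − nn) ·
  [ Σₖ (S(t*, u_{k−1}) − S(t*, u_k)) (1−p)^{k−1} + S(t*, u_m) (1−p)^m ]`.
  The bracketed *never-seen-again tail* mixes every explanation of an empty
  end of history: death in some inter-survey interval (missing only the
  surveys actually survived) or survival with nondetection throughout.

The joint posterior over hazard parameters and the detection probability
`p` (uniform(0,1) prior) is sampled with adaptive random-walk Metropolis
(componentwise; a hit-and-run variant is included), with Geweke,
Brooks–Gelman–Rubin, DIC, and posterior-predictive-check diagnostics.
A smoothed age profile is available through an intrinsic first-order
random-walk prior, and missing 0/1 covariates are marginalized over
Bernoulli priors with estimated probability parameters.

The package also ships the surrounding study machinery: an exact
piecewise-exponential simulator with a percent-bias/RMSE evaluation
harness, a sample-composition experiment, a generator for synthetic
shorebird-chick datasets with transmitter failure, and plain-text IO
(encounter CSV, schedule JSON, samples CSV with a run manifest).

## A worked example

Simulate one two-season scenario — annual survival 0.25 under a
hunting:nonhunting hazard ratio of 2 (season days 274–365), detection 0.2,
40 known-fate plus 40 marked animals over 477 days with weekly surveys —
and fit the integrated model:

```r
library(eventfuse)
cfg <- sim_config(annual_survival = 0.25, detection_p = 0.2,
                  n_radio = 40, n_marked = 40)
set.seed(7)
sim <- simulate_dataset(cfg)
fit <- eventfuse(sim$data, sim$schedule, family = "seasonal",
                 control = mcmc_control(n_iter = 10000, seed = 7))
summary(fit)
#> Posterior summary (family: seasonal )
#>           mean     sd mc_error   q025   q500   q975
#> lambda1 0.0027 0.0004    0e+00 0.0020 0.0026 0.0035
#> lambda2 0.0081 0.0019    1e-04 0.0046 0.0081 0.0122
#> p       0.2090 0.0113    4e-04 0.1878 0.2088 0.2319
round(cfg$rates, 5)
#> nonhunting    hunting
#>    0.00303    0.00607
```

`lambda1` and `lambda2` are the off- and in-season daily mortality hazards
and `p` the per-survey detection probability of a marked animal; on this
single dataset the posteriors bracket the generating values (0.00303,
0.00607, 0.2).  `coef()`, `confint()`, `predict()` (survival/hazard
curves), `plot()` (traces, or the age-hazard envelope for the random-walk
family), `dic_fit()` and `posterior_predictive_check()` complete the
fitted-model surface.  Averaged over replicated datasets the posterior
means are nearly unbiased — that replication is what
`evaluate_scenario()` and the acceptance script below do.

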