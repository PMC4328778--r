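---
title: "Integrated event-time survival analysis with known and unknown fates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated event-time survival analysis with known and unknown fates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(eventfuse)
```

## The problem

Continuous-time (event-time) survival analysis needs event times, at least
up to an interval.  Wildlife studies rarely deliver them for every animal:
radio-collared individuals are checked repeatedly and their death times are
interval-censored between the last check alive and the first check dead,
but individuals carrying only a mark (or a failed transmitter) are seen
intermittently and their deaths are never observed.  Dropping those animals
wastes data and can bias inference; treating a last sighting as a death
time is simply wrong.

`eventfuse` fits one hazard function jointly to both kinds of record by
adding an explicit model of the detection process for the unknown-fate
animals.  Because both likelihood components share the hazard parameters,
the marked animals inform the hazard (and the known-fate animals sharpen
the detection estimate indirectly), which is what makes the approach an
integrated analysis rather than two analyses glued together.

## The model

Time is continuous, measured in days.  The mortality hazard $h(u)$ is
piecewise constant, either on calendar time (e.g. an off-season rate
$\lambda_1$ and an in-season rate $\lambda_2$ repeating every 365 days) or
on age (daily intervals).  Covariates enter log-linearly as proportional
hazards, $h_i(u) = h_0(u)\exp(x_i'\beta)$, so $e^{\beta_j}$ is a hazard
ratio; continuous covariates are standardized (mean 0, sd 1) and the
recorded centering/scaling makes effects reversible to the raw scale.
Survival over $[t_0, t_1]$ is $S(t_0,t_1)=\exp\{-\int_{t_0}^{t_1}
h_i(u)\,du\}$, computed exactly by summing rate times overlap per constant
segment (no quadrature error; cumulative hazards are exactly additive over
partitions).

**Known-fate records** (entry $e_i$, last alive $r_i$, first dead $s_i$,
possibly $s_i=\infty$) contribute
$S(e_i,r_i)\,[1-S(r_i,s_i)]$, or $S(e_i,r_i)$ when right-censored.
Conditioning on survival to $e_i$ handles staggered entry (left
truncation).  A per-survey Bernoulli detection term for these animals is
available behind a flag but off by default: a functioning transmitter
usually makes detection far easier than for marked animals, so assuming a
shared detection probability would be wrong more often than not.

**Marked records** (entry $e_j$, detection history over the surveys
`stimes`, $nn_j$ sightings, last seen at $t^*_j$) contribute three
elements: survival to the last sighting, $S(e_j, t^*_j)$; the detection
process up to the last sighting, which with constant $p$ collapses from a
product of Bernoulli trials to the binomial kernel
$p^{nn_j}(1-p)^{n_j - nn_j}$ with $n_j$ the number of surveys between
entry and $t^*_j$; and the *never-seen-again tail* -- the probability of
the empty remainder of the history.  With remaining survey times
$u_1<\dots<u_m$ (and $u_0 = t^*_j$),

$$\Pr(\text{nothing after } t^*_j) \;=\; \sum_{k=1}^{m}
\bigl[S(t^*_j,u_{k-1}) - S(t^*_j,u_k)\bigr](1-p)^{k-1}
\;+\; S(t^*_j,u_m)(1-p)^m.$$

Death acts as a competing risk that censors all later detection
opportunities; the post-death latent histories sum to one and drop out,
which is why each death interval carries only the misses that actually
happened.  The joint log-likelihood is the sum of all per-record
contributions under independent death times.

Two boundary conventions matter and are fixed throughout: hazard intervals
are half-open $[a, b)$, and an animal dying exactly at a survey time
counts as dead before that survey (a measure-zero choice that keeps the
simulator and the likelihood consistent).  The final tail element runs to
the last survey; time between the last survey and the administrative study
end carries no observation and is treated as uninformative.  Never-seen
marked animals are supported ($t^* = e_j$), as are marked animals
recovered dead (the tail is replaced by an interval-death term).

## Priors and posterior

Detection gets the Bayes--Laplace uniform(0,1) prior.  Log baseline rates
get flat priors on a wide interval (uniform(-12, 0) by default, i.e. daily
rates between $e^{-12}$ and 1; the chick models use uniform(-5, 5) to
match their scale).  Coefficients default to uniform(-5, 5), with
`prior_preset()` also offering a central $t_5$ and a Gaussian(0, 2.24) for
prior-sensitivity comparisons.

The smoothed age profile uses an intrinsic first-order random-walk (RW1)
prior on daily age effects: adjacent ages should have similar log hazards.
With row-standardized neighbor weights (1/2 for interior intervals, 1 at
the boundaries) the matrix $I-H$ is singular, so the implied Gaussian is
improper in the level direction; we therefore implement the standard
intrinsic density $-(k-1)\log\tau - \tfrac{1}{2\tau^2}\sum_i
(a_{i+1}-a_i)^2$ with a sum-to-zero constraint, letting the model
intercept carry the level.  Inside the sampler the constraint is enforced
by construction: the free parameters are the $k-1$ increments
$\delta_i \sim N(0,\tau^2)$ and the effects are the centered cumulative
sum.  The scale $\tau$ is treated as the increment *standard deviation*
with a uniform(0, 5) prior.  (The alternative reading of $\tau^2$ as a
precision is internally inconsistent with putting a uniform prior on "the
standard deviation parameter"; we resolved in favor of the prior
statement.)

Missing 0/1 covariates (the two sex variables in the chick study) get
Bernoulli priors whose probability parameters $\pi$ carry Gaussian(0.5,
0.05) hyperpriors -- a sex ratio constrained to roughly 45--55%.  Rather
than carrying the missing values as discrete MCMC parameters, the
likelihood marginalizes them analytically: each evaluation mixes the
per-individual likelihood over the $\le 4$ configurations of missing
values with weights $\pi^x(1-\pi)^{1-x}$.  This integrates out exactly
what two-point Gibbs steps would sample, mixes better, and leaves $\pi$
with the identical marginal posterior; per-individual imputation
probabilities remain available from the posterior draws by two-point
enumeration.

## Sampling and diagnostics

The default sampler is adaptive componentwise random-walk Metropolis:
per-parameter Gaussian proposals whose log step sizes adapt towards an
acceptance rate of 0.35 (componentwise proposals mix well anywhere in
0.23--0.44) with a diminishing Robbins--Monro schedule during burn-in,
frozen afterwards so the retained chain satisfies detailed balance.
Burn-in defaults to half the iterations.  A hit-and-run variant (uniform
random direction, scalar adaptive step) is provided as
`algorithm = "harm"`; both satisfy the same stationarity contract, and the
two-season model additionally runs through a compiled
sufficient-statistic likelihood whose sampler is tested against the
generic one.  Chains are reproducible: chain $c$ seeds the RNG with
`seed + c - 1`, and identical configuration and data give bitwise
identical draws.  An all-rejecting chain (acceptance below $10^{-3}$
after adaptation) warns rather than failing silently.

Diagnostics are pure functions of the draws: Geweke's early/late-window
z-score with spectral-density-at-zero variances from a Bartlett lag
window of length $4\sqrt{n/100}$ (the classical test names no estimator;
this is a conventional choice, recorded here); the corrected
Brooks--Gelman--Rubin scale reduction factors per parameter plus the
multivariate factor; DIC as $\bar D + p_D$ with $p_D = \bar D -
D(\bar\theta)$; batch-means Monte Carlo errors; and posterior predictive
checks that simulate replicate failure ages for the known deaths
(conditional on entry and on dying within the study) and report the
Bayesian p-value of a mean-failure-age or per-individual-difference
discrepancy.

## The simulation engine

The simulation design uses a two-season year: study day 1 is 1 January
and the in-season (hunting) window is days 274--365 of each 365-day year
(no leap years).  The design anchor is a convention -- only the window's
dates, not the study's calendar start, are inherent to the design -- and
it is recorded in the configuration.  Given an annual survival $S$ and an
in:off-season hazard ratio $r$, the daily rates solve
$\exp\{-\lambda_1(365-92) - r\lambda_1\,92\} = S$ in closed form, e.g.
$S=0.25 \Rightarrow (\lambda_1,\lambda_2)=(0.0030, 0.00607)$ per day.

Death times are drawn by the exact two-step scheme: first the death
interval from the multinomial whose probabilities are the
geometric-style products $q_k = \prod_{l<k} e^{-\lambda_l t_{l}}\,(1 -
e^{-\lambda_k t_{k}})$ over the individual-specific segment lengths
(staggered entry makes the partition individual-specific), then the time
within the chosen interval from the truncated exponential by inverse CDF.
The resulting law is exactly piecewise-exponential, verified against the
closed-form CDF at $10^5$ draws.  Entries are uniform on integer days
1--30; surveys are weekly at days 7, 14, ... (the weekly phase is another
recorded convention); known-fate deaths are bracketed to the containing
survey interval; marked animals get Bernoulli detections at each survey
they are alive for and are always right-censored.  Studies run 477 days,
or 1569 days at annual survival 0.85 so enough deaths occur for
estimation.

The evaluation harness replicates simulate--fit--summarize, reporting
percent bias of the mean posterior mean and the RMSE of posterior means
per parameter, with a per-chain Geweke screen that flags (never silently
drops) suspect replicates.  One replicate = one dataset + one chain;
replicate seeds derive from a master seed, and the composition experiment
reuses the same replicate seeds at every grid point (common random
numbers) so RMSE comparisons across compositions are sharpened.  The
package's standard problem sizes are 100 replicates of 10,000 iterations
(half burn-in) for a scenario, chosen as a sensible
accuracy/computation trade-off for routine reruns of the whole grid; the
full-scale protocol (hundreds of chains, tens of thousands of iterations)
is a matter of passing larger numbers to the same functions.

## The synthetic chick study

`generate_plover_dataset()` emulates the structure of a shorebird-chick
telemetry study: chicks tagged at 1 day of age, checked daily until 30
days, a piecewise age hazard with elevated mortality before age 4 days,
proportional-hazards covariates (standardized mass and tarsus, habitat
and year dummies, two 0/1 sex covariates with missing entries), and
transmitter failure that converts a chick from known fate to unknown fate
partway through its record.  Failure is modeled as the earlier of battery
exhaustion (15 days plus geometric jitter, mean 18) and an
exponential-onset early malfunction; the malfunction rate (0.12/day)
was calibrated once so that roughly 39% of fates are known, matching the
share reported in the field study the scenario is styled after.  After
failure the chick is searched for daily and detected with constant
probability (default 0.75) while alive.  Default effect sizes are
plausible field-scale values (e.g. mass about $-0.35$ per sd,
agricultural habitat about $-0.52$ on the log-hazard scale).

Two selection effects of this design are worth knowing about when
interpreting checks run against it.  First, the known-death subsample is
selected by transmitter survival: under heavy early failure, chicks whose
deaths are observed are disproportionately those that died *early*, so a
posterior predictive check that replicates failure ages conditional only
on death-within-study will see observed ages truncated young and report
extreme p-values even under the true model; calibration checks of the PPC
therefore use the all-known-fate generator variant (long battery, no
malfunction), where the conditioning matches the data.  Second, covariate
heterogeneity left out of a fit acts as frailty, which makes the marginal
hazard decline smoothly within each age region; model-comparison
exercises on generated data must include the generating covariates, or
the smoothed random-walk model will (correctly) beat the two-level
piecewise model that generated the conditional hazards.

What the generator does **not** emulate -- and hence what passing tests do
not establish about real data: spatial search structure (detection is one
constant, not distance- or observer-dependent), dependence of detection on
transmitter state beyond the known/unknown split, brood-level clustering,
covariate measurement error, and model misspecification of the hazard
itself (fits recover a generator of the same family).  Bias/RMSE results
under the matched model should be read as best-case performance.

`fit_case_models()` runs the three-model ladder (constant / piecewise at
age 4 / random-walk age effects) sharing covariates and detection, ranks
the models by DIC, and `ph_assumption_check()` refits the winner with
covariate-by-(standardized) age interactions for every covariate whose
credible interval excludes zero, reporting whether each interaction's
interval includes zero -- inclusion is consistent with proportional
hazards.  An age-by-year interaction is never tested: the random-walk
model already absorbs shared temporal structure in age.

## Numerical choices

All likelihood work is in log space; $\log(1-e^{-H})$ uses the
numerically stable branch split at $\log 2$; tail mixtures are clipped at
$10^{-300}$ before logging.  Piecewise integration is exact (rate times
overlap), so the quadrature comparisons in the test suite hold to
$10^{-10}$.  Proposal scales start at 0.5 on the working scale;
starting values are drawn from dispersed uniforms (log rates in $(-9,-3)$
for the seasonal model, detection in $(0.05, 0.95)$).  Degenerate inputs
fail loudly: empty datasets, non-increasing survey times, $r \ge s$,
constant chains in the Geweke test, single chains in the BGR factor.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(annual_survival = 0.25, detection_p = 0.2,
                  n_radio = 40, n_marked = 40)
set.seed(7)
sim <- simulate_dataset(cfg)
fit <- eventfuse(sim$data, sim$schedule, family = "seasonal",
                 control = mcmc_control(n_iter = 10000, seed = 7))
summary(fit)
cfg$rates  # the generating daily rates
```

## Known limitations

Detection probability is a single constant per dataset (no per-survey or
individual covariates on $p$); Weibull or spline hazards are out of
scope; the composition and bias summaries assume the fitted family
matches the generator.  The grid families require daily surveys on an
integer axis -- the natural geometry of the chick study -- while arbitrary
schedules are handled by the generic likelihood functions.
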