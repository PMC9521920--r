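---
title: "Models and methods in elkdyn"
author: "elkdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in elkdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`elkdyn` implements a complete analysis chain for long-term ungulate
demographic series — here, Roosevelt elk counted on islands of the Kodiak
Archipelago — against climate, predator-abundance, and timber-harvest
covariates. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## The scientific setting

Two responses are modelled. *Early calf recruitment* is the age ratio
(calves per 100 adult females) from mid-summer composition surveys, pooled
across the herds of a group. *Abundance* is the September aerial count of
the one herd (Raspberry Island) where canopy cover permits full counts;
elk are harvested each fall *after* the count, and the harvest is known.
Candidate drivers are organised into five non-exclusive hypotheses —
winter severity, spring nutritional bottleneck, summer–autumn maternal
carryover, predation, and timber harvest — each represented by several
correlated covariates.

## Covariate engineering

Seasonal windows are fixed: winter 1 Nov–31 Mar (labelled by the ending
year, so "winter" predictors align with the following summer's response),
spring 1 Apr–31 May, summer 1 Jun–31 Aug, fall 1 Sep–31 Oct. All
maternal-carryover predictors (summer, fall, growing degree days, drought
indices, first fall freeze) and timber-stand areas are paired with
response year *t* from calendar year *t − 1*, exactly once; winter and
spring predictors come from year *t*.

Choices the data sources do not dictate, made once and applied everywhere:

* **Freeze threshold.** A freeze day is `tmin <= 0` °C. First fall freeze
  is searched over 1 Aug–31 Dec of *t − 1*, last spring freeze over
  1 Jan–30 Jun of *t*; these windows bracket observed freeze dates in
  subpolar maritime climates with wide margin. Winter duration is the
  calendar-day difference.
* **Mean monthly minimum winter temperature** is the mean over the five
  winter months of each month's minimum daily `tmin`. The alternative
  reading (mean of daily minima) is available via
  `derive_seasonal_metrics(..., monthly_min = "daily")`.
* **Growing degree days** use the daily-average method,
  `max(0, (tmax + tmin)/2 - 5)`, base 5 °C, no upper cutoff, summed over
  June–August.
* **Missing data.** Each seasonal metric tolerates up to 10% missing days
  per window (configurable); beyond that the year's value is marked
  missing and a warning is logged.

### Drought indices (SPEI)

The standardized precipitation–evapotranspiration index transforms the
monthly climatic water balance `D = P - PET` into standard-normal
deviates. Potential evapotranspiration follows Thornthwaite: the annual
heat index comes from the 12-month temperature climatology, and monthly
PET scales with astronomical day length and month length; months at or
below 0 °C evaporate nothing. Trailing *k*-month sums of `D` are fitted
*per calendar month* with a three-parameter log-logistic distribution by
unbiased probability-weighted moments over the calibration period, and
the fitted CDF values are mapped through `qnorm`.

* The forest index is the 6-month scale evaluated in July (window
  Feb–Jul). A 7-month Jan–Jul window is available through
  `build_predictor_table(..., spei6_window = "jan_jul")` for the
  alternative reading of "January–July".
* The grassland index is the 3-month scale evaluated in September
  (Jul + Aug + Sep).
* Near-symmetric or negatively skewed samples yield the mirrored
  (upper-bounded) member of the log-logistic family — shape and scale both
  negative — which is handled transparently; fitted CDF values are clamped
  to `[1e-7, 1 - 1e-7]` before the normal quantile. A truly constant
  aggregate series, or fewer than 30 calibration values for a month, is an
  error.

## Downing reconstruction of predator abundance

Brown bear abundance is reconstructed from harvest-at-age (cementum-aged
known-mortality) data by Downing cohort reconstruction, a deterministic
minimum-population method. Conventions:

* Classes `1..m-1` are single-year ages `0..m-2`; class `m` is open
  (ages `>= m-1`). Under this reading the cohort recursion
  `N[i,t] = H[i,t] + N[i+1,t+1]` is well defined after collapsing age
  classes; the default is `m = 5`.
* Un-aged mortalities in a year are allocated proportionally to that
  year's aged class distribution (equivalently, aged counts are divided by
  the proportion aged), so row totals equal total known mortalities.
  Uniform allocation is available for years with no aged animals.
* The two oldest classes are closed by the equal-harvest-mortality-rate
  assumption: `H[m-1,t]/N[m-1,t] = H[m,t]/N[m,t]`, combined with the
  harvest-only balance
  `N[m-1,t] + N[m,t] = H[m-1,t] + H[m,t] + N[m,t+1]`. When the needed
  class-(m−1) harvest is zero the year falls back to the minimum-alive
  value, logged. A pure minimum-alive closure is available via
  `closure = "minimum_alive"`.
* The terminal year is initialised at its own harvest (minimum alive), and
  the final `m - 1` years — whose cohorts' future harvests are unobserved —
  are dropped from the output with a truncation record.

Reconstructed totals are kept fractional internally and are a *minimum*
estimate; they are used as an abundance index, not corrected for the
method's known underestimation.

## Recruitment model

For each herd group, the age ratio is modelled as
`y_t ~ Normal(b0 + sum_k b_k z_kt, sigma^2)` on predictors standardized by
their sample mean and SD over exactly the modelled years. Priors are
diffuse: `Normal(0, 100)` on coefficients and `Uniform(0, 100)` on the
residual SD — at a response scale of roughly 16–57 calves per 100 cows
these are effectively flat, and halving or doubling them moves posterior
means by a small fraction of a posterior SD (tested). Sampling is by a
conjugate-conditional Gibbs sampler (the model is linear-Gaussian, so both
full conditionals are exact draws); defaults are 3 chains of 50,000
iterations, burn-in 10,000, thinning 5. Posterior means match ordinary
least squares to Monte-Carlo error, which the test suite uses as an
independent oracle.

Diagnostics: rank-normalised split-chain R-hat per parameter (threshold
1.1, warning on exceedance — never silent acceptance); an influence flag
per coefficient (95% credible interval excluding zero); and a posterior
predictive p-value. The default discrepancy is the sum of squared
standardized residuals. Because the residual SD adapts to the data, this
discrepancy is nearly blind to isolated outliers (its p-value stays near
0.5); `discrepancy = "max"` (maximum absolute standardized residual) is
provided for outlier-sensitive checking. Effect sizes are translated to
the response scale as `beta_hat * (max - min) / sd`, the predicted change
across a predictor's observed range with the others held at their means.

## Abundance model

The count series is modelled with a Gompertz state-space model with
explicit harvest. With `x_t` the log of true abundance and `H_t` the known
post-count removal, the post-harvest log abundance is
`q_t = log(exp(x_t) - H_t)` and

```
x_t   = q_{t-1} + a + b q_{t-1} + sum_k c_k z_kt + eps_t,   eps_t ~ N(0, sigma_proc)
log C_t ~ Normal(x_t, sigma_obs)
```

Harvest is subtracted on the natural scale before the Gompertz step
(biologically: the fall hunt removes animals after the September survey).
Any year in which recorded harvest reaches the observed count is rejected
before fitting. Interior missing counts are linearly interpolated first
and flagged.

Numerical choices:

* Sampling runs through JAGS with per-chain seeds, 3 chains, and the same
  iteration schedule as the recruitment model. The density-dependence term
  is sampled in centred form, `b (q_{t-1} - qbar)` with `qbar` the mean log
  count, which removes the strong posterior correlation between `a` and
  `b`; draws are transformed back to the raw parameterization
  (`a = a_centred - b*qbar`) before summarising, so reported parameters
  refer to the equation above.
* The initial state has prior `Normal(log C_1, sd 2)`; states in years
  with harvest are truncated below at `log(H_t + 0.001)` so the
  post-harvest abundance stays positive during sampling.
* Coefficient priors are `Normal(0, 100)`; the error-SD priors are uniform
  with an upper bound of 10, generous on the log scale.
* The posterior predictive check uses the observation equation (sum of
  squared standardized log-count residuals).

Because the density-dependence coefficient in a Gompertz model with
covariates is only weakly identified in a state-space setting, it tends to
be overestimated in magnitude when observation error is present; the
package therefore also provides the Dennis–Taper parametric bootstrap
likelihood-ratio test as an independent check.

## Density-dependence test

On the observed counts, the alternative model is the stochastic Ricker
form `log(N_{t+1}/N_t) = a + b N_t + sigma Z`, the null fixes `b = 0`
(random walk with drift on the log scale), and the statistic is
`Lambda = 2(l1 - l0)` with the variance profiled out. The null
distribution comes from `n_boot` (default 2,000) series simulated from the
fitted null with the same length and initial count; the p-value uses the
add-one rule `(1 + #{boot >= obs}) / (1 + n_boot)` and is bit-reproducible
given the seed. The test deliberately uses the Ricker form (`b N_t`) per
the test's original formulation while the state-space model uses the
Gompertz form (`b log N_t`); the asymmetry is intentional. By default the
test runs on observed counts without harvest adjustment. The
`N_t` versus `log(N_{t+1}/N_t)` diagnostic point set is returned for
plotting (growth from year `t` to `t + 1` against abundance in year `t`).

## Predictor selection

Selection is two-stage. First, a univariate OLS screen computes each
candidate's R² against the response over overlapping years. Second, one
representative per hypothesis is chosen so that no chosen pair has
`|r| > 0.7` (Pearson, pairwise complete cases). The search is exhaustive
over one-candidate-per-hypothesis combinations (including dropping a
hypothesis whose candidates are exhausted), maximizing first the number of
hypotheses retained, then total R², with lexicographic tie-breaks — this
makes the substitution rule deterministic where a greedy formulation would
be ambiguous about re-checking the other member of a conflicting pair.
Candidates per hypothesis are capped (default 6, in decreasing R² order)
to bound the enumeration.

## The synthetic-data generator

Every input has a seeded generator sized to the study system: 63 years of
counts, ~47 of age ratios, ~51 of predator mortalities, an aged fraction
of 0.92, and Kodiak-like climate normals (annual mean near 4 °C, seasonal
half-range 7.5 °C, ~1.8 m annual precipitation).

* **Weather**: annual temperature sinusoid plus Gaussian daily noise,
  wet-day gamma precipitation, snowfall when the daily mean is below
  freezing, and an accumulate-and-melt snow-depth bucket. It does *not*
  emulate synoptic autocorrelation, atmospheric-river events, or station
  relocations, so tests on it validate the aggregation arithmetic, not
  robustness to real-weather pathologies.
* **Predator population**: age-structured projection with recruitment,
  natural survival, binomial harvest, and binomial aging of mortalities.
  In deterministic mode (continuous-valued, proportional harvest, natural
  survival 1, everyone harvested on reaching the oldest tracked age) the
  population satisfies the Downing assumptions *exactly*, giving an
  end-to-end oracle in which reconstruction must reproduce simulator truth
  to floating-point accuracy on all non-truncated years.
* **Elk system**: counts are drawn from the exact state-space generative
  process above (including the harvest rule and lognormal observation
  error) and age ratios from the exact linear recruitment model; herd-level
  composition counts are spread from the ratio series with Poisson cow and
  binomial calf counts. Passing recovery tests therefore demonstrates
  correctness of the fitting machinery under the assumed model, not
  robustness to sightability bias or misclassification, which the real
  surveys acknowledge and the package does not model.

Default generating values for the elk system (`a = 1.45`, `b = -0.27`,
`sigma_proc = 0.23`, `sigma_obs = 0.20`, winter-temperature effect 0.14,
recruitment intercept 33 with residual SD ~7–8, predation effect −3.4 and
fall-freeze effect +2.8 on the standardized scale) are the scale of
effects this kind of analysis reports, so recovery tests mirror realistic
power.

## Problem sizes used in the checks

The automated checks run at sizes chosen to give informative Monte-Carlo
resolution while staying light: interval-coverage checks use 100
replicates of the n = 44 recruitment model (3 chains × 4,000 iterations)
and 20 replicates of the 63-year state-space model (3 chains × 9,000
iterations); the density-dependence null calibration uses 200 replicates
with 500 bootstrap draws each; SPEI standardization uses a 70-year monthly
calibration. The full MCMC defaults (50,000 iterations) are intended for
actual analyses.

## Known limitations

* The Downing closure formula is one defensible reading of the equal-rate
  assumption; published applications rarely print their terminal-class
  arithmetic, so `closure` is exposed for comparison against any reference
  reconstruction.
* The recruitment models assume independent Gaussian errors; age-ratio
  series can be overdispersed and autocorrelated.
* Density dependence and environmental covariates are only weakly
  separable in 60-year series; the state-space estimate of `b` should be
  read jointly with the bootstrap test.
* The pipeline's abundance-model screening uses the realized log growth
  rate as the screening response, a pragmatic stand-in for refitting the
  state-space model per candidate.
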