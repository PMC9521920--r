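# elkdyn

Drivers of ungulate population dynamics from long-term monitoring data.
`elkdyn` implements the full analysis chain used to ask which of five
non-exclusive hypotheses — winter severity, spring nutritional bottleneck,
summer–autumn maternal carryover, predation, and timber harvest — best
explain variation in elk early calf recruitment (calves per 100 adult
females) and September population counts, in a system (the Kodiak
Archipelago) where brown bears are the only wild predator and their
abundance must itself be reconstructed from harvest records.

It is written for quantitative wildlife ecologists who have: daily weather
station records; predator harvest-at-age (cementum-aged mortality) data;
herd composition counts and population counts with known harvest; and
timber-stand harvest histories.

## What it computes

* **Covariates** (`build_predictor_table`): seasonal temperature, precipitation,
  snow, freeze-date, and winter-duration predictors; growing degree days
  (base 5 °C); Thornthwaite potential evapotranspiration and the
  standardized precipitation–evapotranspiration index (SPEI), fitted per
  calendar month by unbiased probability-weighted moments of a
  three-parameter log-logistic distribution; timber areas by stand-age
  class. Carryover and timber predictors are lagged one year.
* **Predator reconstruction** (`downing_reconstruct`): Downing cohort
  reconstruction of minimum abundance *N<sub>t</sub>* from harvest-at-age
  data, with proportional allocation of un-aged mortalities, an
  equal-mortality-rate closure of the two oldest age classes, and
  truncation of the last *m* − 1 years.
* **Data preparation** (`filter_composition_counts`, `aggregate_age_ratios`,
  `interpolate_missing_counts`, `standardize_predictors`, `linear_trend`):
  reasoned record filtering with an exclusion log, pooled age ratios,
  linear interpolation of missing counts, and OLS trend tests.
* **Predictor selection** (`univariate_r2_screen`, `select_representatives`):
  per-hypothesis univariate R² screening, then an exhaustive
  conflict-resolution step keeping pairwise |*r*| ≤ 0.7 while maximizing
  the number of hypotheses retained.
* **Recruitment model** (`fit_recruitment_glm`): Bayesian linear model
  *y<sub>t</sub>* ~ Normal(β₀ + Σ β<sub>k</sub> z<sub>kt</sub>, σ²) with
  diffuse priors, sampled by Gibbs; rank-normalised split-chain R̂,
  posterior predictive p-values, and effect sizes over observed predictor
  ranges.
* **Abundance model** (`fit_gompertz_ssm`): Bayesian Gompertz state-space
  model with explicit harvest,
  *x<sub>t</sub>* = *q<sub>t−1</sub>* + *a* + *b q<sub>t−1</sub>* +
  Σ *c<sub>k</sub> z<sub>kt</sub>* + ε<sub>t</sub>, where
  *q<sub>t</sub>* = log(e<sup>*x<sub>t</sub>*</sup> − *H<sub>t</sub>*)
  removes the known post-count harvest on the natural scale, and
  log-counts are observed with error.
* **Density-dependence test** (`dennis_taper_test`): the Dennis–Taper
  parametric bootstrap likelihood-ratio test of *b* = 0 in
  log(*N<sub>t+1</sub>*/*N<sub>t</sub>*) = *a* + *b N<sub>t</sub>* + σZ,
  with a seeded, bit-reproducible bootstrap.
* **Synthetic data** (`simulate_daily_weather`, `simulate_bear_harvest`,
  `simulate_elk_system`, ...): seeded generators for every input, sized to
  the study system, so the entire pipeline runs and is tested without any
  external data.
* **Orchestration** (`run_pipeline`): one call from config to screening
  tables, model summaries, trend tables, exclusion logs, and a run
  manifest.

## Worked example

Reconstruct a predator population from simulated harvest-at-age records,
then ask whether predator abundance depresses calf recruitment:

```r
library(elkdyn)

bear <- simulate_bear_harvest(n_years = 51, seed = 2, aged_fraction = 0.92)
H <- build_harvest_matrix(bear$records, n_classes = 5)
recon <- downing_reconstruct(H)
print(recon)
#> Downing population reconstruction (equal_rate closure)
#> Years 1967-2013; dropped 4 terminal years (2014, 2015, 2016, 2017)
#> Reconstructed abundance: mean 90.6, range 44-129

tr <- linear_trend(recon$year, recon$total)
# slope 1.31 bears/yr, R^2 = 0.525, p = 8.5e-09: a long-term increase

z <- data.frame(year = 1967:2013,
                bear = as.numeric(scale(recon$total)))
sim <- simulate_elk_system(years = 1967:2013, seed = 3, covariates = z,
                           beta = c(intercept = 33, bear = -4.4),
                           resid_sd = 8)
d <- merge(sim$ratios, z, by = "year")
fit <- fit_recruitment_glm(ratio ~ bear, d,
                           mcmc_config(iterations = 20000,
                                       burn_in = 5000, thin = 5, seed = 4))
print(fit)
#> Bayesian recruitment model: ratio ~ bear
#> n = 47; 3 chains x 20000 iterations (burn-in 5000, thin 5)
#> Convergence: ok (max R-hat 1.000); Bayesian p-value 0.522
#>  parameter   mean    sd  lower  upper rhat influential
#>  intercept 32.567 1.140 30.361 34.861    1        TRUE
#>       bear -4.971 1.144 -7.237 -2.708    1        TRUE
#>      sigma  7.693 0.848  6.270  9.605    1        TRUE

response_range_effect(fit, "bear", range(recon$total),
                      sd = sd(recon$total))
#> [1] -16.98
```

Reading the output: the reconstruction recovers a predator index rising
by about 1.3 bears per year; the recruitment model's standardized
predator coefficient is −4.97 calves per 100 cows per SD of predator
abundance, with a 95% credible interval excluding zero
(`influential = TRUE`); across the observed range of reconstructed
abundance that amounts to a decline of about 17 calves per 100 cows. The
Bayesian p-value near 0.5 indicates adequate model fit, and R̂ = 1.00
indicates converged chains. The generating value here was −4.4, inside
the interval.

The full pipeline, end to end on synthetic inputs:

```r
res <- run_pipeline(list(seed = 1), out_dir = "out")
summary(res$abundance)      # Gompertz state-space posterior
res$ddtest                  # Dennis-Taper bootstrap p-value
```

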