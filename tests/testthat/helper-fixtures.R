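# Fixture builders shared across test files.

# Daily series with every field constant; spans whole calendar years.
constant_weather <- function(years, tmean = 2, tmin = tmean - 3,
                             tmax = tmean + 3, precip = 2, snowfall = 0,
                             snow_depth = 0) {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  data.frame(date = dates, tmin = tmin, tmax = tmax, tmean = tmean,
             precip = precip, snowfall = snowfall, snow_depth = snow_depth)
}

# Deterministic harvest-only predator population satisfying the Downing
# assumptions exactly: survival 1, uniform harvest below the terminal age,
# everyone harvested on reaching age 3 (so the open 5th class stays empty).
exact_downing_sim <- function(n_years = 30, seed = 7, n0 = 200,
                              rate = 0.2) {
  hmax <- 200L
  hr <- c(rep(rate, 3), 1, rep(0, hmax - 3))
  simulate_bear_harvest(n_years = n_years, seed = seed, n0 = n0,
                        recruit_rate = 0.3, survival = 1,
                        harvest_rate = hr, aged_fraction = 1,
                        max_age = hmax, stochastic = FALSE)
}

# Standardized covariate table over a year span.
std_covariate <- function(years, seed, name = "z") {
  set.seed(seed)
  out <- data.frame(year = years, z = as.numeric(scale(rnorm(length(years)))))
  names(out)[2] <- name
  out
}
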