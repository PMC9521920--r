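# Seeded synthetic-data generators emulating every pipeline input: daily
# subpolar-maritime weather, an age-structured predator population with
# harvest-at-age reporting, Gompertz count dynamics with harvest and
# lognormal observation error, and herd composition counts consistent with
# a linear recruitment model on standardized covariates.  Defaults are
# sized to the study system: 63 years of counts, 44 of age ratios, about
# 50 years of predator mortalities, an aged fraction of 0.92, and Kodiak-
# like climate normals (annual mean near 4 deg C, winters hovering around
# freezing, roughly 1.7 m of annual precipitation).

#' Simulate daily weather
#'
#' Daily minimum/maximum temperature from an annual sinusoid plus Gaussian
#' noise, wet-day gamma precipitation, snowfall when the day's mean is
#' below freezing, and a simple accumulate-and-melt snow depth bucket.
#'
#' @param years integer vector of calendar years to cover.
#' @param seed integer seed; the series is bit-reproducible given
#'   (arguments, seed).
#' @param mean_temp annual mean temperature, deg C (default 4).
#' @param amplitude seasonal half-range, deg C (default 7.5).
#' @param noise_sd daily temperature noise SD, deg C (default 2.5).
#' @param diurnal_range mean tmax - tmin spread, deg C (default 6).
#' @param wet_prob probability a day is wet (default 0.45).
#' @param precip_shape,precip_scale gamma parameters of wet-day
#'   precipitation in mm (defaults 0.9 and 12 give ~1.8 m/yr).
#' @param warming linear trend in deg C per decade (default 0).
#' @return data frame \code{date}, \code{tmin}, \code{tmax}, \code{tmean},
#'   \code{precip}, \code{snowfall}, \code{snow_depth}.
#' @export
simulate_daily_weather <- function(years, seed = 1L, mean_temp = 4,
                                   amplitude = 7.5, noise_sd = 2.5,
                                   diurnal_range = 6, wet_prob = 0.45,
                                   precip_shape = 0.9, precip_scale = 12,
                                   warming = 0) {
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  doy <- as.numeric(format(dates, "%j"))
  yfrac <- (as.numeric(format(dates, "%Y")) - min(years)) +
    doy / 365.25
  seasonal <- mean_temp - amplitude * cos(2 * pi * (doy - 15) / 365.25) +
    warming / 10 * yfrac
  tmean <- seasonal + stats::rnorm(length(dates), 0, noise_sd)
  half <- pmax(0.5, diurnal_range / 2 +
                 stats::rnorm(length(dates), 0, diurnal_range / 8))
  tmin <- tmean - half
  tmax <- tmean + half
  wet <- stats::runif(length(dates)) < wet_prob
  precip <- ifelse(wet,
                   stats::rgamma(length(dates), precip_shape,
                                 scale = precip_scale), 0)
  snowfall <- ifelse(tmean < 0, precip * 10, 0)  # snow depth ~10x water
  depth <- numeric(length(dates))
  d <- 0
  melt_rate <- 15  # mm depth per degree-day above freezing
  for (i in seq_along(dates)) {
    d <- d + snowfall[i]
    if (tmean[i] > 0) d <- max(0, d - melt_rate * tmean[i])
    depth[i] <- d
  }
  data.frame(date = dates, tmin = tmin, tmax = tmax, tmean = tmean,
             precip = precip, snowfall = snowfall, snow_depth = depth)
}

#' Simulate an age-structured predator population with harvest-at-age data
#'
#' Projects an age-structured population forward with recruitment, natural
#' survival, and harvest, recording each year's mortalities and which were
#' aged.  In deterministic mode the projection is continuous-valued and
#' harvest is an exact proportion of each age, which makes the population
#' satisfy the Downing reconstruction assumptions exactly when natural
#' survival is 1.
#'
#' @param n_years number of data years (default 51).
#' @param seed integer seed.
#' @param n0 initial total abundance (default 90).
#' @param recruit_rate age-0 recruits per head per year (default 0.19).
#' @param survival annual natural survival probability (default 0.93).
#' @param harvest_rate annual harvest probability per head, scalar or
#'   per-age vector (default 0.1).
#' @param aged_fraction probability a mortality is aged (default 0.92).
#' @param max_age oldest tracked age (default 25; deterministic mode uses
#'   at least 200 so that unharvested tail mass is negligible).
#' @param stochastic draw demographic events binomially (default TRUE);
#'   \code{FALSE} gives the exact proportional projection.
#' @param start_year first calendar year (default 1967).
#' @return list with \code{records} (data frame \code{year}, \code{age};
#'   \code{NA} age for un-aged mortalities), \code{truth} (data frame
#'   \code{year}, \code{N} total abundance), and the generating parameters.
#' @export
simulate_bear_harvest <- function(n_years = 51L, seed = 1L, n0 = 90,
                                  recruit_rate = 0.19, survival = 0.93,
                                  harvest_rate = 0.1,
                                  aged_fraction = 0.92, max_age = 25L,
                                  stochastic = TRUE,
                                  start_year = 1967L) {
  set.seed(seed)
  if (!stochastic) max_age <- max(max_age, 200L)
  ages <- 0:max_age
  h <- rep_len(harvest_rate, length(ages))
  # initialise near the stationary age distribution
  stable <- cumprod(c(1, rep(survival, max_age) * (1 - h[-length(h)])))
  N <- n0 * stable / sum(stable)
  if (stochastic) N <- round(N)
  years <- seq(start_year, length.out = n_years)
  rec_year <- integer(0); rec_age <- integer(0)
  truth <- numeric(n_years)
  Hmat <- matrix(0, n_years, length(ages),
                 dimnames = list(seq(start_year, length.out = n_years),
                                 ages))
  for (t in seq_len(n_years)) {
    truth[t] <- sum(N)
    if (sum(N) < 1) {
      warning("population extinct in year ", years[t], "; series truncated",
              call. = FALSE)
      truth <- truth[seq_len(t - 1)]
      years <- years[seq_len(t - 1)]
      break
    }
    harv <- if (stochastic) stats::rbinom(length(N), round(N), h) else N * h
    Hmat[t, ] <- harv
    n_mort <- if (stochastic) sum(harv) else round(sum(harv))
    if (n_mort > 0) {
      if (stochastic) {
        morts <- rep(ages, harv)
        aged <- stats::runif(length(morts)) < aged_fraction
        rec_year <- c(rec_year, rep(years[t], length(morts)))
        rec_age <- c(rec_age, ifelse(aged, morts, NA_integer_))
      } else {
        # deterministic: report every mortality, fully aged, rounded counts
        cnt <- round(harv)
        morts <- rep(ages, cnt)
        rec_year <- c(rec_year, rep(years[t], length(morts)))
        rec_age <- c(rec_age, morts)
      }
    }
    surv <- if (stochastic) {
      stats::rbinom(length(N), round(N) - harv, survival)
    } else (N - harv) * survival
    recruits <- if (stochastic) stats::rpois(1, recruit_rate * sum(N))
                else recruit_rate * sum(N)
    N <- c(recruits, surv[-length(surv)])
    # survivors of the oldest age stay in it (open class)
    N[length(N)] <- N[length(N)] + surv[length(surv)]
  }
  list(records = data.frame(year = rec_year, age = rec_age),
       harvest_by_age = Hmat[seq_along(years), , drop = FALSE],
       truth = data.frame(year = years, N = truth),
       params = list(n0 = n0, recruit_rate = recruit_rate,
                     survival = survival, harvest_rate = harvest_rate,
                     aged_fraction = aged_fraction,
                     stochastic = stochastic))
}

#' Simulate the elk count and recruitment system
#'
#' Generates a September count series from the exact Gompertz state-space
#' process used by \code{\link{fit_gompertz_ssm}} (harvest removed on the
#' natural scale after each count, lognormal observation error) and an age-
#' ratio series from the exact linear recruitment model used by
#' \code{\link{fit_recruitment_glm}}.
#'
#' @param years integer vector of years (default 1958:2020, 63 years).
#' @param seed integer seed.
#' @param covariates data frame with \code{year} plus standardized covariate
#'   columns; may be NULL for covariate-free dynamics.
#' @param a,b Gompertz intercept and density dependence on log abundance
#'   (defaults 1.45, -0.27).
#' @param c_cov named numeric vector of growth-equation coefficients for
#'   columns of \code{covariates} (default none).
#' @param sigma_proc,sigma_obs process and observation SDs on the log scale
#'   (defaults 0.23, 0.20).
#' @param n1 initial true abundance (default 100).
#' @param harvest_frac fraction of the observed count removed after each
#'   survey (default 0.1); set 0 for no harvest.
#' @param beta named numeric vector of recruitment coefficients; the
#'   \code{"intercept"} element is required (default intercept 33,
#'   residual-scale units of calves per 100 cows).
#' @param resid_sd recruitment residual SD (default 8).
#' @param ratio_years years for which age ratios are generated (default
#'   \code{years}); the ratio covariates need only cover these.
#' @param ratio_covariates covariate table for the recruitment model
#'   (default \code{covariates}).
#' @return list \code{counts} (year, count, harvest), \code{ratios}
#'   (year, ratio), \code{truth} (log abundance series and parameters).
#' @export
simulate_elk_system <- function(years = 1958:2020, seed = 1L,
                                covariates = NULL,
                                a = 1.45, b = -0.27, c_cov = NULL,
                                sigma_proc = 0.23, sigma_obs = 0.20,
                                n1 = 100, harvest_frac = 0.1,
                                beta = c(intercept = 33), resid_sd = 8,
                                ratio_years = years,
                                ratio_covariates = covariates) {
  set.seed(seed)
  T_ <- length(years)
  Z <- NULL
  if (!is.null(covariates) && length(c_cov)) {
    Z <- as.matrix(covariates[match(years, covariates$year), names(c_cov),
                              drop = FALSE])
    if (anyNA(Z)) stop("covariates must cover all years")
  }
  x <- numeric(T_); count <- numeric(T_); H <- numeric(T_)
  x[1] <- log(n1)
  count[1] <- exp(x[1] + stats::rnorm(1, 0, sigma_obs))
  H[1] <- floor(harvest_frac * min(count[1], exp(x[1])))
  for (t in 2:T_) {
    post <- exp(x[t - 1]) - H[t - 1]
    if (post <= 0) stop("harvest rule drove abundance to zero in year ",
                        years[t - 1])
    q <- log(post)
    drift <- q + a + b * q +
      if (is.null(Z)) 0 else sum(c_cov * Z[t, ])
    x[t] <- drift + stats::rnorm(1, 0, sigma_proc)
    count[t] <- exp(x[t] + stats::rnorm(1, 0, sigma_obs))
    H[t] <- floor(harvest_frac * min(count[t], exp(x[t])))
  }
  counts <- data.frame(year = years, count = count, harvest = H)

  # recruitment ratios from the linear model on the covariate table
  ratios <- NULL
  if (!is.null(beta)) {
    stopifnot("intercept" %in% names(beta))
    slopes <- beta[setdiff(names(beta), "intercept")]
    Zr <- if (length(slopes)) {
      m <- as.matrix(ratio_covariates[match(ratio_years,
                                            ratio_covariates$year),
                                      names(slopes), drop = FALSE])
      if (anyNA(m)) stop("ratio covariates must cover all ratio years")
      m
    } else NULL
    mu <- beta[["intercept"]] +
      if (is.null(Zr)) 0 else as.numeric(Zr %*% slopes)
    ratios <- data.frame(year = ratio_years,
                         ratio = mu + stats::rnorm(length(ratio_years), 0,
                                                   resid_sd))
  }
  list(counts = counts, ratios = ratios,
       truth = list(log_abundance = data.frame(year = years, x = x),
                    params = list(a = a, b = b, c_cov = c_cov,
                                  sigma_proc = sigma_proc,
                                  sigma_obs = sigma_obs,
                                  harvest_frac = harvest_frac,
                                  beta = beta, resid_sd = resid_sd)))
}

#' Simulate a timber-stand harvest table
#'
#' Seeded stand records (harvest year and area) emulating intermittent
#' early logging followed by sustained commercial harvest.
#'
#' @param years harvest years with any logging activity.
#' @param seed integer seed.
#' @param mean_area mean stand area per harvest year, km^2 (default 2).
#' @param activity probability a year sees any harvest (default 0.8).
#' @return data frame \code{harvest_year}, \code{area}.
#' @export
simulate_timber_stands <- function(years, seed = 1L, mean_area = 2,
                                   activity = 0.8) {
  set.seed(seed)
  act <- years[stats::runif(length(years)) < activity]
  data.frame(harvest_year = act,
             area = stats::rgamma(length(act), shape = 2,
                                  scale = mean_area / 2))
}

#' Spread an age-ratio series into herd composition counts
#'
#' Generates per-herd cow/calf/bull counts whose pooled ratio is centred on
#' the target series, for exercising the filtering and aggregation stages.
#'
#' @param ratios data frame \code{year}, \code{ratio}.
#' @param herds character vector of herd names.
#' @param seed integer seed.
#' @param cows_per_herd expected cows counted per herd (default 40).
#' @return composition data frame \code{year}, \code{herd}, \code{cows},
#'   \code{calves}, \code{bulls}.
#' @export
simulate_composition_counts <- function(ratios, herds, seed = 1L,
                                        cows_per_herd = 40) {
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrow(ratios)), function(i) {
    cows <- stats::rpois(length(herds), cows_per_herd)
    calves <- stats::rbinom(length(herds), cows,
                            pmin(0.95, ratios$ratio[i] / 100))
    bulls <- stats::rpois(length(herds), cows_per_herd * 0.4)
    data.frame(year = ratios$year[i], herd = herds,
               cows = cows, calves = calves, bulls = bulls)
  }))
  rownames(out) <- NULL
  out
}
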