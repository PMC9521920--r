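test_that("simulators are bit-reproducible given the seed", {
  w1 <- simulate_daily_weather(2000:2002, seed = 71)
  w2 <- simulate_daily_weather(2000:2002, seed = 71)
  expect_identical(w1, w2)
  b1 <- simulate_bear_harvest(n_years = 20, seed = 72)
  b2 <- simulate_bear_harvest(n_years = 20, seed = 72)
  expect_identical(b1, b2)
  e1 <- simulate_elk_system(years = 1990:2010, seed = 73)
  e2 <- simulate_elk_system(years = 1990:2010, seed = 73)
  expect_identical(e1, e2)
  expect_false(identical(w1, simulate_daily_weather(2000:2002, seed = 99)))
})

test_that("simulated weather honours its configured moments and constraints", {
  w <- simulate_daily_weather(1990:2009, seed = 74, mean_temp = 4,
                              noise_sd = 2.5)
  expect_true(all(w$tmin <= w$tmax))
  expect_true(all(w$precip >= 0 & w$snowfall >= 0 & w$snow_depth >= 0))
  expect_true(all(w$snowfall[w$tmean >= 0] == 0))
  se <- sd(w$tmean) / sqrt(nrow(w) / 30)  # generous: ~monthly independence
  expect_lt(abs(mean(w$tmean) - 4), 3 * se + 0.3)
})

test_that("noise-free weather freezes where the seasonal curve crosses zero", {
  w <- simulate_daily_weather(2000:2002, seed = 75, mean_temp = 3,
                              amplitude = 15, noise_sd = 0,
                              diurnal_range = 0)
  # tmin = tmean - 0.5 = 3 - 15 cos(2 pi (doy - 15)/365.25) - 0.5
  doy <- as.numeric(format(w$date, "%j"))
  an <- 3 - 15 * cos(2 * pi * (doy - 15) / 365.25) - 0.5
  expect_equal(w$tmin, an, tolerance = 1e-12)
  fm <- freeze_metrics(w, 2002)
  fall <- w$date >= as.Date("2001-08-01") & w$date <= as.Date("2001-12-31")
  expect_equal(unname(fm["first_fall_freeze"]),
               as.numeric(format(min(w$date[fall & w$tmin <= 0]), "%j")))
})

test_that("bear harvest reporting matches the aged fraction", {
  sim <- simulate_bear_harvest(n_years = 60, seed = 76,
                               aged_fraction = 0.92)
  frac <- mean(!is.na(sim$records$age))
  n <- nrow(sim$records)
  expect_lt(abs(frac - 0.92), 3 * sqrt(0.92 * 0.08 / n))
  # truth series aligns with the recorded years
  expect_true(all(sort(unique(sim$records$year)) %in% sim$truth$year))
})

test_that("zero harvest produces no records and reconstruction refuses", {
  sim <- simulate_bear_harvest(n_years = 15, seed = 77, harvest_rate = 0)
  expect_equal(nrow(sim$records), 0)
  Hc <- collapse_age_classes(sim$harvest_by_age, 0:4)
  expect_error(downing_reconstruct(Hc), "empty harvest table")
})

test_that("noise-free elk dynamics reduce to geometric growth", {
  sim <- simulate_elk_system(years = 2000:2019, seed = 78, a = 0.1, b = 0,
                             sigma_proc = 0, sigma_obs = 0,
                             harvest_frac = 0, n1 = 100, beta = NULL)
  expect_equal(sim$counts$count, 100 * exp(0.1 * (0:19)), tolerance = 1e-9)
})

test_that("recruitment ratios follow the configured linear model", {
  z <- std_covariate(1990:2019, seed = 79, name = "bear")
  sim <- simulate_elk_system(years = 1990:2019, seed = 80, covariates = z,
                             beta = c(intercept = 33, bear = -4),
                             resid_sd = 0.01)
  expect_equal(sim$ratios$ratio, 33 - 4 * z$bear, tolerance = 0.05)
})

test_that("synthetic tables round-trip through the package readers", {
  tmp <- withr::local_tempdir()
  w <- simulate_daily_weather(2000:2001, seed = 81)
  write_table(w, file.path(tmp, "w.csv"))
  w2 <- read_daily_weather(file.path(tmp, "w.csv"))
  expect_equal(w2, w, tolerance = 1e-12)

  cnt <- simulate_elk_system(years = 2000:2015, seed = 82)$counts
  write_table(cnt, file.path(tmp, "c.csv"))
  c2 <- read_count_series(file.path(tmp, "c.csv"))
  expect_equal(c2, cnt, tolerance = 1e-12)

  comp <- simulate_composition_counts(
    data.frame(year = 2000:2005, ratio = 33), herds = c("A", "B"),
    seed = 83)
  write_table(comp, file.path(tmp, "comp.csv"))
  expect_equal(read_composition_counts(file.path(tmp, "comp.csv")), comp)
})

test_that("GHCN-style column names are accepted by the weather reader", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(DATE = c("2000-01-01", "2000-01-02"),
                       TMIN = c(-5, -3), TMAX = c(1, 2),
                       PRCP = c(0, 4), SNOW = c(0, 30), SNWD = c(10, 35)),
            tmp, row.names = FALSE)
  d <- read_daily_weather(tmp)
  expect_equal(d$tmin, c(-5, -3))
  expect_equal(d$tmean, c(-2, -0.5))
  expect_equal(d$snow_depth, c(10, 35))
})
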