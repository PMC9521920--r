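test_that("seasonal means and totals recover constant inputs", {
  w <- constant_weather(1999:2001, tmean = 2, precip = 2)
  m <- derive_seasonal_metrics(w, 2001)
  expect_equal(unname(m["mean_winter_temp"]), 2)
  expect_equal(unname(m["mean_spring_temp"]), 2)
  # spring precip: 61 days x 2 mm
  expect_equal(unname(m["spring_precip"]), 122)
  # summer window belongs to the prior year (92 days)
  expect_equal(unname(m["summer_precip"]), 184)
})

test_that("growing degree days vanish at the base temperature and are monotone", {
  w <- constant_weather(1999:2001, tmean = 5, tmin = 5, tmax = 5)
  m <- derive_seasonal_metrics(w, 2001)
  expect_equal(unname(m["gdd"]), 0)

  w2 <- w
  idx <- which(w2$date == as.Date("2000-07-01"))
  w2$tmax[idx] <- w2$tmax[idx] + 4   # daily mean rises 2 deg above base
  m2 <- derive_seasonal_metrics(w2, 2001)
  expect_equal(unname(m2["gdd"]), 2)
  expect_gte(m2["gdd"], m["gdd"])
})

test_that("winter monthly-minimum mean matches a brute-force scan", {
  w <- constant_weather(1999:2001)
  doy <- as.numeric(format(w$date, "%j"))
  set.seed(42)
  w$tmin <- -5 + 8 * sin(2 * pi * doy / 365) + rnorm(nrow(w), 0, 2)
  m <- derive_seasonal_metrics(w, 2001)
  win <- w[w$date >= as.Date("2000-11-01") & w$date <= as.Date("2001-03-31"), ]
  oracle <- mean(sapply(split(win$tmin, format(win$date, "%Y-%m")), min))
  expect_equal(unname(m["mean_monthly_min_winter_temp"]), oracle)
})

test_that("fully missing windows yield NA with a warning", {
  w <- constant_weather(1999:2001)
  w$tmean[format(w$date, "%m") %in% c("04", "05") &
            format(w$date, "%Y") == "2001"] <- NA
  expect_warning(m <- derive_seasonal_metrics(w, 2001), "missing")
  expect_true(is.na(m["mean_spring_temp"]))
})

test_that("freeze dates and winter duration follow the threshold rule", {
  w <- constant_weather(1999:2001, tmin = 5)
  # no freeze at all
  expect_true(all(is.na(freeze_metrics(w, 2001))))

  w$tmin[w$date == as.Date("2000-09-20")] <- -1
  w$tmin[w$date >= as.Date("2001-01-10") & w$date <= as.Date("2001-05-10") &
           format(w$date, "%d") == "10"] <- 0   # freezes incl. May 10
  fm <- freeze_metrics(w, 2001)
  expect_equal(unname(fm["first_fall_freeze"]),
               as.numeric(format(as.Date("2000-09-20"), "%j")))
  expect_equal(unname(fm["last_spring_freeze"]),
               as.numeric(format(as.Date("2001-05-10"), "%j")))
  expect_equal(unname(fm["winter_duration"]),
               as.numeric(as.Date("2001-05-10") - as.Date("2000-09-20")))
  expect_equal(unname(fm["winter_duration"]), 232)
})

test_that("timber areas bin stands exactly", {
  s <- data.frame(harvest_year = c(2020, 2017, 2010, 1980),
                  area = c(1, 1, 1, 1))
  a <- timber_age_class_areas(s, 2020)
  expect_equal(unname(a), c(1, 1, 1, 1, 4))

  one <- data.frame(harvest_year = 2020, area = 2)
  expect_equal(unname(timber_age_class_areas(one, 2020)),
               c(2, 0, 0, 0, 2))
  expect_error(timber_age_class_areas(one, 2019), "after query year")

  set.seed(1)
  rnd <- data.frame(harvest_year = sample(1960:2020, 40, replace = TRUE),
                    area = runif(40, 0.1, 5))
  a2 <- timber_age_class_areas(rnd, 2020)
  age <- 2020 - rnd$harvest_year
  oracle <- c(sum(rnd$area[age < 1]),
              sum(rnd$area[age >= 1 & age <= 5]),
              sum(rnd$area[age >= 6 & age <= 30]),
              sum(rnd$area[age > 30]), sum(rnd$area))
  expect_equal(unname(a2), oracle)
})

test_that("the predictor table lags carryover and timber predictors once", {
  yrs <- 1995:2005
  w <- constant_weather(1993:2005)
  # encode the calendar year into the summer temperature
  yr <- as.numeric(format(w$date, "%Y"))
  mo <- as.numeric(format(w$date, "%m"))
  w$tmean <- ifelse(mo %in% 6:8, yr - 1900, 2)
  stands <- data.frame(harvest_year = 1996, area = 3)
  tab <- build_predictor_table(w, yrs, stands = stands,
                               bear = data.frame(year = yrs,
                                                 abundance = yrs * 2))
  expect_equal(tab$mean_summer_temp, yrs - 1 - 1900)
  # stand harvested 1996 is age <1 when evaluated for response year 1997
  expect_equal(tab$timber_lt1[tab$year == 1997], 3)
  expect_equal(tab$timber_lt1[tab$year == 1998], 0)
  expect_equal(tab$timber_1_5[tab$year == 1998], 3)
  # predator abundance joins unlagged
  expect_equal(tab$bear_abundance, yrs * 2)
})
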