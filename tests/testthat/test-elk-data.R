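make_comp <- function() {
  data.frame(
    year = c(2000, 2000, 2001, 2001, 2002, 2003, 2006, 2006),
    herd = c("A", "B", "A", "B", "A", "A", "A", "B"),
    cows = c(10, 50, 40, 30, NA, 25, 2, 1),
    calves = c(12, 20, 10, 0, 5, 8, 1, 1),
    bulls = c(2, 10, 5, 4, 3, 6, 0, 0))
}

test_that("composition filters drop records for the stated reasons", {
  out <- filter_composition_counts(make_comp(), min_group_total = 5)
  ex <- out$excluded
  expect_equal(ex$reason[ex$year == 2000 & ex$herd == "A"],
               "calves_exceed_cows")
  expect_equal(ex$reason[ex$year == 2001 & ex$herd == "B"], "zero_calves")
  expect_equal(ex$reason[ex$year == 2002], "adults_unknown")
  # 2006 group total = 5 -> whole year dropped
  expect_true(all(ex$reason[ex$year == 2006] ==
                    "group_total_below_threshold"))
  expect_false(2006 %in% out$retained$year)
  # partition: every input row lands in exactly one bucket
  expect_equal(nrow(out$retained) + nrow(out$excluded), nrow(make_comp()))
  # idempotence
  again <- filter_composition_counts(out$retained, min_group_total = 5)
  expect_equal(again$retained, out$retained)
  expect_equal(nrow(again$excluded), 0)
})

test_that("blocklisted herds are excluded with their own reason", {
  cc <- make_comp()
  out <- filter_composition_counts(cc, blocklist = "B")
  expect_false("B" %in% out$retained$herd)
  expect_true(all(out$excluded$reason[out$excluded$herd == "B"] ==
                    "herd_blocklisted"))
})

test_that("age ratios pool counts rather than averaging per-herd ratios", {
  rec <- data.frame(year = c(2000, 2000), herd = c("A", "B"),
                    cows = c(50, 50), calves = c(10, 23),
                    bulls = c(5, 5))
  ar <- aggregate_age_ratios(rec)
  expect_equal(ar$ratio, 33)

  one <- data.frame(year = 2001, herd = "A", cows = 100, calves = 33,
                    bulls = 10)
  expect_equal(aggregate_age_ratios(one)$ratio, 33)

  set.seed(21)
  rnd <- data.frame(year = rep(2000:2009, each = 4),
                    herd = rep(letters[1:4], 10),
                    cows = rpois(40, 40) + 1,
                    calves = rpois(40, 12),
                    bulls = rpois(40, 15))
  ar2 <- aggregate_age_ratios(rnd)
  oracle <- sapply(2000:2009, function(y)
    100 * sum(rnd$calves[rnd$year == y]) / sum(rnd$cows[rnd$year == y]))
  expect_equal(ar2$ratio, oracle)
  # pooled ratio lies within the per-herd range each year
  per_herd <- 100 * rnd$calves / rnd$cows
  for (y in 2000:2009) {
    rng <- range(per_herd[rnd$year == y])
    expect_gte(ar2$ratio[ar2$year == y], rng[1])
    expect_lte(ar2$ratio[ar2$year == y], rng[2])
  }
})

test_that("interpolation fills interior gaps linearly and flags them", {
  s <- data.frame(year = c(2000, 2003, 2004), count = c(90, 120, 100))
  out <- interpolate_missing_counts(s)
  expect_equal(out$count, c(90, 100, 110, 120, 100))
  expect_equal(out$imputed, c(FALSE, TRUE, TRUE, FALSE, FALSE))

  full <- data.frame(year = 2000:2004, count = 11:15)
  expect_equal(interpolate_missing_counts(full)$count, 11:15)

  set.seed(22)
  yrs <- 2000:2030
  obs <- sort(c(1, length(yrs), sample(2:(length(yrs) - 1), 12)))
  s2 <- data.frame(year = yrs[obs], count = runif(length(obs), 50, 200))
  out2 <- interpolate_missing_counts(s2)
  oracle <- approx(s2$year, s2$count, xout = yrs)$y
  expect_equal(out2$count, oracle)
  expect_equal(out2$count[match(s2$year, out2$year)], s2$count)

  expect_error(interpolate_missing_counts(
    data.frame(year = c(2001, 2003), count = c(NA, 5))), "observed")
})

test_that("standardization is exact and invertible", {
  d <- data.frame(year = 1:3, a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize_predictors(d)
  expect_equal(z$a, c(-1, 0, 1))
  sc <- attr(z, "scaling")
  for (v in c("a", "b")) {
    mu <- sc$mean[sc$predictor == v]; s <- sc$sd[sc$predictor == v]
    expect_equal(z[[v]] * s + mu, d[[v]], tolerance = 1e-14)
  }
  d$c <- 7
  expect_error(standardize_predictors(d), "constant.*: c")
})

test_that("linear trends match a normal-equations oracle", {
  tr <- linear_trend(2000:2010, 2 * (2000:2010) + 1)
  expect_equal(tr$slope, 2)
  expect_equal(tr$r.squared, 1)

  set.seed(23)
  x <- 1970:2010; y <- 0.4 * x + rnorm(41, 0, 5)
  tr2 <- linear_trend(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(tr2$slope, beta[2], tolerance = 1e-10)
  expect_equal(tr2$intercept, beta[1], tolerance = 1e-10)
  rss <- sum((y - X %*% beta)^2)
  expect_equal(tr2$r.squared, 1 - rss / sum((y - mean(y))^2),
               tolerance = 1e-10)
  expect_error(linear_trend(1:2, 1:2), "at least 3")
})
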