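short_mcmc <- function(seed = 3) {
  mcmc_config(iterations = 6000, burn_in = 1000, thin = 2, seed = seed)
}

make_glm_data <- function(n = 44, beta = c(33, 2, -4, 0), sd = 7,
                          seed = 41) {
  set.seed(seed)
  Z <- sapply(1:3, function(k) as.numeric(scale(rnorm(n))))
  y <- beta[1] + Z %*% beta[-1] + rnorm(n, 0, sd)
  data.frame(ratio = as.numeric(y), z1 = Z[, 1], z2 = Z[, 2], z3 = Z[, 3])
}

test_that("posterior means agree with OLS under diffuse priors", {
  d <- make_glm_data()
  fit <- fit_recruitment_glm(ratio ~ z1 + z2 + z3, d, short_mcmc())
  ols <- coef(lm(ratio ~ z1 + z2 + z3, d))
  ndraw <- nrow(fit$draws$beta)
  mcse <- apply(fit$draws$beta, 2, sd) / sqrt(ndraw / 10)  # conservative ESS
  expect_true(all(abs(coef(fit) - ols) < 3 * mcse + 0.05))
  expect_true(fit$converged)
  expect_true(all(fit$summary$rhat < 1.1))
})

test_that("pure-noise responses give slope intervals covering zero", {
  set.seed(42)
  d <- make_glm_data(beta = c(33, 0, 0, 0), seed = 42)
  fit <- fit_recruitment_glm(ratio ~ z1 + z2 + z3, d, short_mcmc(5))
  s <- fit$summary
  slopes <- s[s$parameter %in% c("z1", "z2", "z3"), ]
  expect_true(all(!slopes$influential))
})

test_that("the posterior predictive p-value behaves as a fit diagnostic", {
  d <- make_glm_data()
  fit <- fit_recruitment_glm(ratio ~ z1 + z2 + z3, d, short_mcmc())
  expect_gt(posterior_predictive_pvalue(fit), 0.2)
  expect_lt(posterior_predictive_pvalue(fit), 0.8)

  d2 <- d
  d2$ratio[10] <- d2$ratio[10] + 10 * 7   # 10-SD outlier
  # the adaptive residual SD hides a lone outlier from the sum-of-squares
  # discrepancy; the max-residual discrepancy flags it
  fit2 <- fit_recruitment_glm(ratio ~ z1 + z2 + z3, d2, short_mcmc(),
                              discrepancy = "max")
  expect_lt(posterior_predictive_pvalue(fit2), 0.1)
  fit3 <- fit_recruitment_glm(ratio ~ z1 + z2 + z3, d, short_mcmc(),
                              discrepancy = "max")
  expect_gt(posterior_predictive_pvalue(fit3), 0.2)
})

test_that("range effects follow the closed form", {
  d <- make_glm_data()
  attr(d, "scaling") <- data.frame(predictor = c("z1", "z2", "z3"),
                                   mean = c(5, 0, 0), sd = c(2, 1, 3))
  fit <- fit_recruitment_glm(ratio ~ z1 + z2 + z3, d, short_mcmc())
  b1 <- fit$summary$mean[fit$summary$parameter == "z1"]
  expect_equal(response_range_effect(fit, "z1", c(1, 9)),
               b1 * 8 / 2)
  expect_equal(response_range_effect(fit, "z2", c(4, 4)), 0)
  expect_error(response_range_effect(fit, "nope", c(0, 1)), "unknown")
})

test_that("posterior summaries are invariant to row order", {
  d <- make_glm_data()
  fit1 <- fit_recruitment_glm(ratio ~ z1 + z2 + z3, d, short_mcmc(9))
  fit2 <- fit_recruitment_glm(ratio ~ z1 + z2 + z3, d[sample(44), ],
                              short_mcmc(9))
  expect_equal(fit1$summary, fit2$summary, tolerance = 1e-12)
})

test_that("results are insensitive to doubling the prior scales", {
  d <- make_glm_data()
  f1 <- fit_recruitment_glm(ratio ~ z1 + z2 + z3, d, short_mcmc())
  cfg2 <- short_mcmc(); cfg2$prior_sd <- 200; cfg2$sigma_upper <- 200
  f2 <- fit_recruitment_glm(ratio ~ z1 + z2 + z3, d, cfg2)
  expect_true(all(abs(f1$summary$mean - f2$summary$mean) <
                    0.05 * f1$summary$sd + 0.02))
})

test_that("model methods are mutually consistent", {
  d <- make_glm_data()
  fit <- fit_recruitment_glm(ratio ~ z1 + z2 + z3, d, short_mcmc())
  expect_equal(unname(predict(fit)),
               unname(as.numeric(fit$X %*% coef(fit))))
  expect_equal(residuals(fit), d$ratio - predict(fit))
  pr <- predict(fit, interval = "credible")
  expect_true(all(pr$lower <= pr$fit & pr$fit <= pr$upper))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(44L, 3L))
  expect_output(print(fit), "Bayesian recruitment model")
})
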