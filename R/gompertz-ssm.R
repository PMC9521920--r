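# Bayesian Gompertz state-space model of September population counts with
# explicit harvest removal.  Latent log abundance x_t; post-harvest log
# abundance q_t = log(exp(x_t) - H_t); growth follows
#   x_t = q_{t-1} + a + b q_{t-1} + sum_k c_k z_{k,t} + eps_t,
# eps_t ~ N(0, sigma_proc), and log counts are observed with error
# sigma_obs.  Harvest is removed on the natural scale after each count
# (fall hunt follows the September survey).  Sampling runs through JAGS.

.ssm_model_string <- function(K) {
  cov_prior <- if (K > 0)
    "  for (k in 1:K) { c[k] ~ dnorm(0, prior_prec) }\n" else ""
  cov_term <- if (K > 0) " + inprod(c[1:K], Z[t, 1:K])" else ""
  paste0(
    "model {\n",
    "  a ~ dnorm(0, prior_prec)\n",
    "  b ~ dnorm(0, prior_prec)\n",
    cov_prior,
    "  sigma_proc ~ dunif(0, sigma_upper)\n",
    "  sigma_obs ~ dunif(0, sigma_upper)\n",
    "  tau_proc <- pow(sigma_proc, -2)\n",
    "  tau_obs <- pow(sigma_obs, -2)\n",
    "  x[1] ~ dnorm(mu1, 0.25) T(lb[1], )\n",
    "  for (t in 2:T) {\n",
    "    q[t-1] <- log(exp(x[t-1]) - H[t-1])\n",
    # centered density-dependence term: decorrelates a and b
    "    mu[t] <- q[t-1] + a + b * (q[t-1] - qbar)", cov_term, "\n",
    "    x[t] ~ dnorm(mu[t], tau_proc) T(lb[t], )\n",
    "  }\n",
    "  for (t in 1:T) { logC[t] ~ dnorm(x[t], tau_obs) }\n",
    "}\n")
}

#' Fit the Bayesian Gompertz state-space abundance model
#'
#' @param counts data frame \code{year}, \code{count} (complete; interpolate
#'   first with \code{\link{interpolate_missing_counts}}).
#' @param harvest data frame \code{year}, \code{harvest} of post-count
#'   removals; years without records are treated as zero harvest.  Every
#'   harvest must be smaller than that year's count.
#' @param covariates optional data frame with \code{year} plus standardized
#'   covariate columns entering the growth equation (matched to the
#'   transition into year t).
#' @param config MCMC settings from \code{\link{mcmc_config}}; on the log
#'   scale of the state equation the Uniform error-prior bound is capped at
#'   10.
#' @param cri credible-interval level (default 0.95).
#' @return object of class \code{gompertz_ssm} with elements \code{summary}
#'   (intercept, density dependence, covariate coefficients, process and
#'   observation SDs), \code{states} (posterior of log abundance),
#'   \code{draws}, \code{bayes_p}, \code{converged}.
#' @export
fit_gompertz_ssm <- function(counts, harvest = NULL, covariates = NULL,
                             config = mcmc_config(), cri = 0.95) {
  yrs <- counts$year
  stopifnot(all(diff(yrs) == 1), all(counts$count > 0))
  T_ <- length(yrs)
  H <- rep(0, T_)
  if (!is.null(harvest)) {
    idx <- match(harvest$year, yrs)
    H[idx[!is.na(idx)]] <- harvest$harvest[!is.na(idx)]
  }
  if (any(H < 0)) stop("negative harvest")
  if (any(H[-T_] >= counts$count[-T_]))
    stop("harvest must be below the observed count in every year")

  Z <- NULL; covnames <- character(0)
  if (!is.null(covariates)) {
    covnames <- setdiff(names(covariates), "year")
    Z <- as.matrix(covariates[match(yrs, covariates$year), covnames,
                              drop = FALSE])
    if (anyNA(Z[-1, ])) stop("covariates must cover years 2..T")
    Z[1, ] <- 0
  }
  K <- length(covnames)

  lb <- ifelse(H > 0, log(H + 1e-3), -20)
  lb[T_] <- -20  # no transition leaves the final year
  qbar <- mean(log(counts$count))
  data <- list(T = T_, logC = log(counts$count), H = H[-T_],
               mu1 = log(counts$count[1]), lb = lb, qbar = qbar,
               prior_prec = 1 / config$prior_sd^2,
               sigma_upper = min(config$sigma_upper, 10))
  if (K > 0) { data$Z <- Z; data$K <- K }

  x_init <- log(pmax(counts$count, c(H[-T_], 0) + 1))
  inits <- lapply(seq_len(config$chains), function(ch)
    list(x = x_init, a = 0, b = 0, sigma_proc = 0.2, sigma_obs = 0.2,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = config$seed + 1000L * ch))

  jm <- rjags::jags.model(textConnection(.ssm_model_string(K)),
                          data = data, inits = inits,
                          n.chains = config$chains,
                          n.adapt = min(1000L, config$burn_in),
                          quiet = TRUE)
  stats::update(jm, config$burn_in, progress.bar = "none")
  vars <- c("a", "b", if (K > 0) "c", "sigma_proc", "sigma_obs", "x")
  n_iter <- config$iterations - config$burn_in
  samp <- rjags::coda.samples(jm, vars, n.iter = n_iter,
                              thin = config$thin, progress.bar = "none")

  getm <- function(name) sapply(samp, function(ch) as.numeric(ch[, name]))
  # back-transform the centered intercept to the raw parameterization
  draws <- list(intercept = getm("a") - getm("b") * qbar,
                density_dependence = getm("b"))
  if (K > 0) for (k in seq_len(K))
    draws[[covnames[k]]] <- getm(if (K == 1) "c" else sprintf("c[%d]", k))
  draws$sigma_proc <- getm("sigma_proc")
  draws$sigma_obs <- getm("sigma_obs")
  summ <- .summarize_draws(draws, cri)
  converged <- all(is.finite(summ$rhat)) && max(summ$rhat) < 1.1
  if (!converged)
    warning("possible non-convergence: max R-hat = ",
            round(max(summ$rhat, na.rm = TRUE), 3), call. = FALSE)

  xdraws <- lapply(seq_len(T_), function(t) getm(sprintf("x[%d]", t)))
  xmat <- sapply(xdraws, function(d) as.numeric(d))   # ndraws x T
  states <- data.frame(year = yrs,
                       mean = colMeans(xmat),
                       lower = apply(xmat, 2, stats::quantile,
                                     (1 - cri) / 2),
                       upper = apply(xmat, 2, stats::quantile,
                                     1 - (1 - cri) / 2))

  # posterior predictive check on the observation equation
  set.seed(config$seed + 777L)
  so <- as.numeric(draws$sigma_obs)
  dev_obs <- colSums((log(counts$count) - t(xmat))^2) / so^2
  dev_rep <- stats::rchisq(length(so), df = T_)
  bayes_p <- mean(dev_rep >= dev_obs)

  structure(list(call = match.call(), years = yrs, counts = counts$count,
                 harvest = H, covnames = covnames,
                 draws = draws, summary = summ, states = states,
                 bayes_p = bayes_p, converged = converged,
                 config = config, cri = cri,
                 scaling = attr(covariates, "scaling")),
            class = "gompertz_ssm")
}

#' Growth-rate change over an observed covariate range
#'
#' Converts a standardized growth-equation coefficient into the change in
#' predicted log growth rate across the observed covariate range:
#' \code{delta_r = c_hat * (max - min) / sd}.
#'
#' @param fit a \code{gompertz_ssm}.
#' @param covariate covariate name.
#' @param range length-2 numeric, observed min and max on the natural scale.
#' @param sd standardization SD; taken from stored scaling when available.
#' @return change in predicted growth rate.
#' @export
growth_rate_covariate_effect <- function(fit, covariate, range, sd = NULL) {
  if (!covariate %in% fit$covnames)
    stop("unknown covariate: ", covariate)
  response_range_effect(fit, covariate, range, sd)
}

#' @export
print.gompertz_ssm <- function(x, ...) {
  cat("Bayesian Gompertz state-space model with harvest\n")
  cat(sprintf("%d years (%d-%d), %d covariates\n", length(x$years),
              min(x$years), max(x$years), length(x$covnames)))
  cat(sprintf("Convergence: %s (max R-hat %.3f); Bayesian p-value %.3f\n",
              if (x$converged) "ok" else "NOT CONVERGED",
              max(x$summary$rhat, na.rm = TRUE), x$bayes_p))
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.gompertz_ssm <- function(object, digits = 3, ...) {
  s <- object$summary
  s[, c("mean", "sd", "lower", "upper", "rhat")] <-
    round(s[, c("mean", "sd", "lower", "upper", "rhat")], digits)
  s
}

#' @export
coef.gompertz_ssm <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' @export
plot.gompertz_ssm <- function(x, ...) {
  plot(x$years, x$counts, pch = 1, xlab = "Year", ylab = "Count",
       ylim = range(c(x$counts, exp(x$states$lower), exp(x$states$upper))),
       ...)
  lines(x$years, exp(x$states$mean), col = "steelblue", lwd = 2)
  lines(x$years, exp(x$states$lower), col = "steelblue", lty = 2)
  lines(x$years, exp(x$states$upper), col = "steelblue", lty = 2)
  invisible(x)
}
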