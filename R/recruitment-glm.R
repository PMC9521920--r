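# Bayesian linear model of calf recruitment (age ratio) on standardized
# predictors, sampled by a conjugate-conditional Gibbs sampler: normal
# coefficient priors, uniform prior on the residual standard deviation.

#' MCMC settings
#'
#' @param chains number of chains (default 3).
#' @param iterations total iterations per chain including burn-in
#'   (default 50000).
#' @param burn_in discarded initial iterations (default 10000).
#' @param thin thinning rate (default 5).
#' @param seed integer seed.
#' @param prior_sd prior standard deviation for coefficients
#'   (Normal(0, prior_sd); default 100).
#' @param sigma_upper upper bound of the Uniform(0, sigma_upper) prior on
#'   the residual SD (default 100).
#' @return list of validated settings.
#' @export
mcmc_config <- function(chains = 3L, iterations = 50000L, burn_in = 10000L,
                        thin = 5L, seed = 1L, prior_sd = 100,
                        sigma_upper = 100) {
  stopifnot(iterations > burn_in, thin >= 1, chains >= 1,
            prior_sd > 0, sigma_upper > 0)
  list(chains = as.integer(chains), iterations = as.integer(iterations),
       burn_in = as.integer(burn_in), thin = as.integer(thin),
       seed = as.integer(seed), prior_sd = prior_sd,
       sigma_upper = sigma_upper)
}

# One Gibbs chain for y ~ N(X beta, sigma^2), beta_j ~ N(0, prior_sd^2),
# sigma ~ U(0, sigma_upper).  Returns retained draws.
.gibbs_lm_chain <- function(y, X, config, chain_seed) {
  set.seed(chain_seed)
  n <- length(y); p <- ncol(X)
  XtX <- crossprod(X); Xty <- crossprod(X, y)
  prior_prec <- diag(1 / config$prior_sd^2, p)
  n_keep <- (config$iterations - config$burn_in) %/% config$thin
  B <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
  S <- numeric(n_keep)
  s2 <- stats::var(y) * stats::runif(1, 0.5, 2)
  k <- 0L
  for (it in seq_len(config$iterations)) {
    V <- chol2inv(chol(XtX / s2 + prior_prec))
    mu <- V %*% (Xty / s2)
    beta <- as.numeric(mu + t(chol(V)) %*% stats::rnorm(p))
    rss <- sum((y - X %*% beta)^2)
    repeat {
      s2 <- 1 / stats::rgamma(1, shape = (n - 1) / 2, rate = rss / 2)
      if (sqrt(s2) < config$sigma_upper) break
    }
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0) {
      k <- k + 1L; B[k, ] <- beta; S[k] <- sqrt(s2)
    }
  }
  list(beta = B, sigma = S)
}

#' Fit the Bayesian recruitment model
#'
#' Linear-Gaussian model \code{ratio ~ Normal(b0 + sum b_k z_k, sigma^2)}
#' fitted by Gibbs sampling under diffuse Normal priors on coefficients and
#' a Uniform prior on the residual SD.  Reports posterior means, SDs, 95
#' percent credible intervals, rank-normalised split-chain R-hat, an
#' influence flag (credible interval excluding zero), and a posterior
#' predictive p-value based on the sum of squared standardized residuals.
#'
#' @param formula model formula, e.g. \code{ratio ~ winter_temp + bear}.
#' @param data data frame holding the response and standardized predictors;
#'   rows with missing values are dropped (complete cases).
#' @param config MCMC settings from \code{\link{mcmc_config}}.
#' @param cri credible-interval level (default 0.95).
#' @param discrepancy discrepancy statistic for the posterior predictive
#'   check: \code{"ssq"} (default; sum of squared standardized residuals)
#'   or \code{"max"} (maximum absolute standardized residual, sensitive to
#'   isolated outliers, which the adaptive residual SD hides from
#'   \code{"ssq"}).
#' @return object of class \code{recruit_fit}.
#' @export
fit_recruitment_glm <- function(formula, data, config = mcmc_config(),
                                cri = 0.95,
                                discrepancy = c("ssq", "max")) {
  discrepancy <- match.arg(discrepancy)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  colnames(X)[colnames(X) == "(Intercept)"] <- "intercept"
  chains <- lapply(seq_len(config$chains), function(ch)
    .gibbs_lm_chain(y, X, config, config$seed + 1000L * ch))

  p <- ncol(X)
  draws <- c(
    stats::setNames(lapply(seq_len(p), function(j)
      sapply(chains, function(ch) ch$beta[, j])), colnames(X)),
    list(sigma = sapply(chains, function(ch) ch$sigma)))
  summ <- .summarize_draws(draws, cri)
  converged <- all(is.finite(summ$rhat)) && max(summ$rhat) < 1.1
  if (!converged)
    warning("possible non-convergence: max R-hat = ",
            round(max(summ$rhat, na.rm = TRUE), 3), call. = FALSE)

  # posterior predictive check on pooled retained draws
  beta_all <- do.call(rbind, lapply(chains, function(ch) ch$beta))
  sigma_all <- unlist(lapply(chains, function(ch) ch$sigma))
  set.seed(config$seed + 777L)
  fitv <- X %*% t(beta_all)                      # n x ndraws
  std_obs <- sweep(y - fitv, 2, sigma_all, "/")
  if (discrepancy == "ssq") {
    T_obs <- colSums(std_obs^2)
    T_rep <- stats::rchisq(length(sigma_all), df = length(y))
  } else {
    T_obs <- apply(abs(std_obs), 2, max)
    z_rep <- matrix(stats::rnorm(length(fitv)), nrow(fitv))
    T_rep <- apply(abs(z_rep), 2, max)
  }
  bayes_p <- mean(T_rep >= T_obs)

  structure(list(call = match.call(), formula = formula,
                 y = y, X = X, n = length(y),
                 draws = list(beta = beta_all, sigma = sigma_all),
                 chains = chains, summary = summ,
                 bayes_p = bayes_p, converged = converged,
                 config = config, cri = cri,
                 scaling = attr(data, "scaling")),
            class = "recruit_fit")
}

#' Posterior predictive p-value
#'
#' Tail probability that replicated data are more discrepant than the
#' observed data, using the sum of squared standardized residuals as the
#' discrepancy; values near 0.5 indicate adequate fit.
#'
#' @param fit a \code{recruit_fit}.
#' @return p-value in [0, 1].
#' @export
posterior_predictive_pvalue <- function(fit) fit$bayes_p

#' Response change over an observed predictor range
#'
#' Converts a standardized coefficient into the predicted change in the
#' response across the observed range of the predictor on its natural
#' scale: \code{delta = beta_hat * (max - min) / sd}, other predictors held
#' at their means.
#'
#' @param fit a \code{recruit_fit} (or \code{gompertz_ssm}).
#' @param predictor predictor name as it appears in the model.
#' @param range length-2 numeric, observed min and max on the natural scale.
#' @param sd the standardization SD of the predictor; taken from the fit's
#'   stored scaling when available.
#' @return predicted change in the response (sign retained).
#' @export
response_range_effect <- function(fit, predictor, range, sd = NULL) {
  summ <- fit$summary
  if (!predictor %in% summ$parameter)
    stop("unknown predictor: ", predictor)
  if (is.null(sd)) {
    sc <- fit$scaling
    if (is.null(sc) || !predictor %in% sc$predictor)
      stop("no stored scaling for ", predictor, "; supply sd")
    sd <- sc$sd[sc$predictor == predictor]
  }
  beta <- summ$mean[summ$parameter == predictor]
  beta * (range[2] - range[1]) / sd
}

#' @export
print.recruit_fit <- function(x, ...) {
  cat("Bayesian recruitment model:",
      deparse(x$formula), "\n")
  cat(sprintf("n = %d; %d chains x %d iterations (burn-in %d, thin %d)\n",
              x$n, x$config$chains, x$config$iterations, x$config$burn_in,
              x$config$thin))
  cat(sprintf("Convergence: %s (max R-hat %.3f); Bayesian p-value %.3f\n",
              if (x$converged) "ok" else "NOT CONVERGED",
              max(x$summary$rhat, na.rm = TRUE), x$bayes_p))
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.recruit_fit <- function(object, digits = 3, ...) {
  s <- object$summary
  s[, c("mean", "sd", "lower", "upper", "rhat")] <-
    round(s[, c("mean", "sd", "lower", "upper", "rhat")], digits)
  s
}

#' @export
coef.recruit_fit <- function(object, ...) {
  b <- colMeans(object$draws$beta)
  stats::setNames(b, colnames(object$X))
}

#' @export
predict.recruit_fit <- function(object, newdata = NULL,
                                interval = c("none", "credible",
                                             "prediction"),
                                level = 0.95, ...) {
  interval <- match.arg(interval)
  X <- if (is.null(newdata)) object$X else {
    tt <- stats::delete.response(stats::terms(object$formula))
    m <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                    na.action = stats::na.pass))
    colnames(m)[colnames(m) == "(Intercept)"] <- "intercept"
    m
  }
  mu <- X %*% t(object$draws$beta)               # n x ndraws
  est <- rowMeans(mu)
  if (interval == "none") return(est)
  a <- (1 - level) / 2
  if (interval == "prediction") {
    mu <- mu + matrix(stats::rnorm(length(mu), 0,
                                   rep(object$draws$sigma,
                                       each = nrow(mu))),
                      nrow(mu))
  }
  data.frame(fit = est,
             lower = apply(mu, 1, stats::quantile, a),
             upper = apply(mu, 1, stats::quantile, 1 - a))
}

#' @export
residuals.recruit_fit <- function(object, ...) {
  object$y - as.numeric(object$X %*% colMeans(object$draws$beta))
}

#' @export
simulate.recruit_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nd <- nrow(object$draws$beta)
  idx <- sample.int(nd, nsim, replace = TRUE)
  out <- sapply(idx, function(i)
    as.numeric(object$X %*% object$draws$beta[i, ]) +
      stats::rnorm(object$n, 0, object$draws$sigma[i]))
  as.data.frame(out)
}

#' @export
plot.recruit_fit <- function(x, ...) {
  est <- predict(x)
  plot(est, x$y, xlab = "Posterior-mean fitted ratio",
       ylab = "Observed ratio", pch = 16, ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
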