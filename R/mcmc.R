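# MCMC summaries and convergence diagnostics shared by the recruitment and
# state-space models.

#' Rank-normalised split-chain R-hat
#'
#' Potential scale reduction factor computed on rank-normalised draws with
#' each chain split in half, so it is sensitive to both location and scale
#' disagreement between chains.
#'
#' @param draws iterations x chains matrix of draws for one parameter.
#' @return scalar R-hat.
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  split <- cbind(draws[1:half, , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  z <- matrix(stats::qnorm((rank(split) - 3 / 8) / (length(split) + 1 / 4)),
              nrow(split), ncol(split))
  m <- ncol(z); nn <- nrow(z)
  mu <- colMeans(z)
  B <- nn * stats::var(mu)
  W <- mean(apply(z, 2, stats::var))
  if (W < 1e-300) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Summarise a named list of draw matrices (iterations x chains) into the
# standard posterior table.
.summarize_draws <- function(draws_list, cri = 0.95) {
  a <- (1 - cri) / 2
  rows <- lapply(names(draws_list), function(p) {
    d <- draws_list[[p]]
    v <- as.numeric(d)
    data.frame(parameter = p, mean = mean(v), sd = stats::sd(v),
               lower = unname(stats::quantile(v, a)),
               upper = unname(stats::quantile(v, 1 - a)),
               rhat = rhat(d))
  })
  out <- do.call(rbind, rows)
  out$influential <- out$lower > 0 | out$upper < 0
  out
}
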