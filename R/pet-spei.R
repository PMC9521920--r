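# Thornthwaite potential evapotranspiration and the standardized
# precipitation-evapotranspiration index (SPEI).  The index transforms a
# k-month trailing climatic water balance through a three-parameter
# log-logistic CDF, fitted per calendar month by unbiased probability-
# weighted moments over a calibration period, into standard-normal deviates.

#' Mean day length by month
#'
#' Astronomical day length (hours) at mid-month from solar declination,
#' used by the Thornthwaite formulation.
#'
#' @param latitude degrees, within +/- 66.
#' @param month integer month 1..12 (vectorised).
#' @return hours of daylight.
#' @export
day_length_hours <- function(latitude, month) {
  stopifnot(abs(latitude) <= 66)
  # mid-month day of year
  J <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)[month]
  delta <- 0.409 * sin(2 * pi * J / 365 - 1.39)
  x <- pmin(1, pmax(-1, -tan(latitude * pi / 180) * tan(delta)))
  24 / pi * acos(x)
}

#' Thornthwaite potential evapotranspiration
#'
#' Monthly PET (mm) from mean monthly temperature and latitude.  The annual
#' heat index I is computed from the 12-month temperature climatology of the
#' supplied series; months at or below 0 deg C contribute nothing and
#' evaporate nothing.
#'
#' @param tmean monthly mean temperature series, deg C.
#' @param latitude degrees.
#' @param month calendar month (1..12) of each element of \code{tmean};
#'   defaults to a repeating Jan..Dec cycle.
#' @param day_length optional day length (hours) per element, overriding the
#'   astronomical value (useful for controlled checks).
#' @return PET in mm per month, same length as \code{tmean}.
#' @export
thornthwaite_pet <- function(tmean, latitude, month = NULL,
                             day_length = NULL) {
  n <- length(tmean)
  if (is.null(month)) month <- rep_len(1:12, n)
  stopifnot(length(month) == n)
  clim <- tapply(tmean, month, mean, na.rm = TRUE)
  clim <- clim[!is.na(clim) & clim > 0]
  if (length(clim) == 0)
    stop("heat index undefined: no month with positive mean temperature")
  I <- sum((clim / 5)^1.514)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  L <- if (is.null(day_length)) day_length_hours(latitude, month)
       else rep_len(day_length, n)
  N <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[month]
  pet <- ifelse(!is.na(tmean) & tmean > 0,
                16 * (L / 12) * (N / 30) * (10 * pmax(tmean, 0) / I)^a,
                ifelse(is.na(tmean), NA_real_, 0))
  as.numeric(pet)
}

# Unbiased probability-weighted moments w0, w1, w2 (decreasing weights,
# w_r = E[X (1 - F(X))^r]) of a sample.
.pwm <- function(x) {
  x <- sort(x)
  n <- length(x)
  j <- seq_len(n)
  w0 <- mean(x)
  w1 <- sum((n - j) / (n - 1) * x) / n
  w2 <- sum((n - j) * (n - j - 1) / ((n - 1) * (n - 2)) * x) / n
  c(w0 = w0, w1 = w1, w2 = w2)
}

# Three-parameter log-logistic fit by unbiased PWM; returns shape (beta),
# scale (alpha), location (gamma).  A near-symmetric or negatively skewed
# sample yields beta < -1 together with alpha < 0, the mirrored
# (upper-bounded) member of the family; the CDF below handles both
# orientations.
.loglogistic_pwm <- function(x) {
  w <- .pwm(x)
  beta <- (2 * w[2] - w[1]) / (6 * w[2] - w[1] - 6 * w[3])
  if (!is.finite(beta) || abs(beta) <= 1)
    stop("degenerate water-balance sample: log-logistic fit failed")
  g12 <- gamma(1 + 1 / beta) * gamma(1 - 1 / beta)
  alpha <- (w[1] - 2 * w[2]) * beta / g12
  gam <- w[1] - alpha * g12
  c(shape = unname(beta), scale = unname(alpha), location = unname(gam))
}

.loglogistic_cdf <- function(x, par) {
  u <- (x - par["location"]) / par["scale"]
  inside <- is.finite(u) & u > 0
  out <- numeric(length(x))
  out[inside] <- 1 / (1 + u[inside]^(-par["shape"]))
  # outside the support: below a lower bound (alpha > 0) the CDF is 0,
  # above an upper bound (alpha < 0) it is 1
  out[!inside] <- if (par["scale"] > 0) 0 else 1
  pmin(1 - 1e-7, pmax(1e-7, out))
}

#' Standardized precipitation-evapotranspiration index
#'
#' Transforms a monthly climatic water balance (precipitation minus PET)
#' into the SPEI at scale \code{scale_k}: trailing k-month sums are fitted,
#' separately per calendar month, with a three-parameter log-logistic
#' distribution by unbiased probability-weighted moments over the
#' calibration period, and the fitted CDF values are mapped through the
#' standard-normal quantile function.
#'
#' @param balance monthly water-balance series (mm).
#' @param year,month calendar labels of each element (consecutive months).
#' @param scale_k aggregation scale in months (e.g. 3 or 6).
#' @param calibration two-element vector \code{c(first, last)} calibration
#'   years (inclusive); at least 30 calibration values are required per
#'   calendar month.
#' @return numeric vector of index values aligned with the input; the first
#'   \code{scale_k - 1} months are \code{NA}.
#' @export
spei_index <- function(balance, year, month, scale_k,
                       calibration = range(year)) {
  n <- length(balance)
  stopifnot(length(year) == n, length(month) == n, scale_k >= 1)
  if (n >= 2) {
    step <- year[-1] * 12 + month[-1] - (year[-n] * 12 + month[-n])
    if (any(step != 1)) stop("monthly series must be consecutive")
  }
  agg <- rep(NA_real_, n)
  cs <- cumsum(ifelse(is.na(balance), 0, balance))
  bad <- cumsum(is.na(balance))
  if (scale_k <= n) {
    i <- scale_k:n
    ok <- (bad[i] - c(0, bad)[i - scale_k + 1]) == 0
    agg[i][ok] <- (cs[i] - c(0, cs)[i - scale_k + 1])[ok]
  }
  out <- rep(NA_real_, n)
  for (m in 1:12) {
    sel <- which(month == m & !is.na(agg))
    cal <- sel[year[sel] >= calibration[1] & year[sel] <= calibration[2]]
    if (length(sel) == 0) next
    if (length(cal) < 30)
      stop(sprintf("insufficient calibration data for month %d (%d values)",
                   m, length(cal)))
    if (stats::sd(agg[cal]) < 1e-10)
      stop(sprintf("degenerate (constant) aggregate series for month %d", m))
    par <- .loglogistic_pwm(agg[cal])
    out[sel] <- stats::qnorm(.loglogistic_cdf(agg[sel], par))
  }
  out
}
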