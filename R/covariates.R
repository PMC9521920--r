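# Seasonal windows used throughout: winter Nov 1 - Mar 31 (labelled by the
# ending year), spring Apr 1 - May 31, summer Jun 1 - Aug 31, fall Sep 1 -
# Oct 31.  Maternal-carryover predictors (summer, fall, growing degree days,
# drought indices, first fall freeze) and timber-stand areas are paired with
# response year t from calendar year t-1; winter and spring predictors from
# year t itself.

.window_days <- function(daily, start, end) {
  daily[daily$date >= start & daily$date <= end, , drop = FALSE]
}

.window_mean <- function(x, n_expected, max_missing) {
  if (sum(!is.na(x)) < (1 - max_missing) * n_expected) return(NA_real_)
  mean(x, na.rm = TRUE)
}

.window_sum <- function(x, n_expected, max_missing) {
  if (sum(!is.na(x)) < (1 - max_missing) * n_expected) return(NA_real_)
  sum(x, na.rm = TRUE)
}

#' Seasonal weather metrics for one response year
#'
#' Computes the seasonal temperature, precipitation, snow, and growing
#' degree-day predictors from a daily weather series.  Winter spans
#' 1 November of \code{year - 1} through 31 March of \code{year}; spring is
#' April-May of \code{year}; summer (June-August) and fall
#' (September-October) are taken from \code{year - 1}, following the
#' carryover-lag convention in which prior growing-season conditions predict
#' the following summer's recruitment.
#'
#' @param daily data frame with columns \code{date} (Date), \code{tmin},
#'   \code{tmax}, \code{tmean} (deg C), \code{precip}, \code{snowfall},
#'   \code{snow_depth} (mm); missing values allowed.
#' @param year integer label of the response year.
#' @param max_missing maximum tolerated fraction of missing days per window
#'   (default 0.1); beyond it the affected metric is \code{NA}.
#' @param monthly_min how to compute the winter minimum-temperature
#'   predictor: \code{"monthly"} (default) averages the five within-month
#'   minima of daily \code{tmin} over November-March; \code{"daily"} averages
#'   daily \code{tmin} directly.
#' @return named numeric vector with elements \code{mean_winter_temp},
#'   \code{mean_monthly_min_winter_temp}, \code{total_snowfall},
#'   \code{mean_snow_depth}, \code{mean_spring_temp}, \code{spring_precip},
#'   \code{mean_summer_temp}, \code{summer_precip}, \code{gdd},
#'   \code{mean_fall_temp}, \code{fall_precip}.
#' @export
derive_seasonal_metrics <- function(daily, year, max_missing = 0.1,
                                    monthly_min = c("monthly", "daily")) {
  monthly_min <- match.arg(monthly_min)
  stopifnot(inherits(daily$date, "Date"))

  win <- .window_days(daily, as.Date(sprintf("%d-11-01", year - 1)),
                      as.Date(sprintf("%d-03-31", year)))
  n_win <- as.numeric(as.Date(sprintf("%d-03-31", year)) -
                      as.Date(sprintf("%d-11-01", year - 1))) + 1
  spr <- .window_days(daily, as.Date(sprintf("%d-04-01", year)),
                      as.Date(sprintf("%d-05-31", year)))
  sum_ <- .window_days(daily, as.Date(sprintf("%d-06-01", year - 1)),
                       as.Date(sprintf("%d-08-31", year - 1)))
  fal <- .window_days(daily, as.Date(sprintf("%d-09-01", year - 1)),
                      as.Date(sprintf("%d-10-31", year - 1)))

  mm_win <- if (monthly_min == "daily") {
    .window_mean(win$tmin, n_win, max_missing)
  } else if (nrow(win) == 0 ||
             sum(!is.na(win$tmin)) < (1 - max_missing) * n_win) {
    NA_real_
  } else {
    mo <- format(win$date, "%Y-%m")
    mean(tapply(win$tmin, mo, min, na.rm = TRUE))
  }

  gdd <- if (nrow(sum_) == 0 ||
             sum(!is.na(sum_$tmin) & !is.na(sum_$tmax)) <
               (1 - max_missing) * 92) {
    NA_real_
  } else {
    sum(pmax(0, (sum_$tmax + sum_$tmin) / 2 - 5), na.rm = TRUE)
  }

  out <- c(
    mean_winter_temp             = .window_mean(win$tmean, n_win, max_missing),
    mean_monthly_min_winter_temp = mm_win,
    total_snowfall               = .window_sum(win$snowfall, n_win, max_missing),
    mean_snow_depth              = .window_mean(win$snow_depth, n_win, max_missing),
    mean_spring_temp             = .window_mean(spr$tmean, 61, max_missing),
    spring_precip                = .window_sum(spr$precip, 61, max_missing),
    mean_summer_temp             = .window_mean(sum_$tmean, 92, max_missing),
    summer_precip                = .window_sum(sum_$precip, 92, max_missing),
    gdd                          = gdd,
    mean_fall_temp               = .window_mean(fal$tmean, 61, max_missing),
    fall_precip                  = .window_sum(fal$precip, 61, max_missing)
  )
  if (anyNA(out)) {
    warning(sprintf("year %d: missing seasonal metrics: %s", year,
                    paste(names(out)[is.na(out)], collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' Freeze-date metrics for one response year
#'
#' First fall freeze is the first day with \code{tmin <= 0} deg C in the
#' 1 August - 31 December window of \code{year - 1}; last spring freeze is
#' the last such day in 1 January - 30 June of \code{year}.  Winter duration
#' is the number of calendar days between them.
#'
#' @inheritParams derive_seasonal_metrics
#' @return named numeric vector \code{first_fall_freeze} (day of year in
#'   \code{year - 1}), \code{last_spring_freeze} (day of year in
#'   \code{year}), and \code{winter_duration} (days); \code{NA} where no
#'   qualifying day exists.
#' @export
freeze_metrics <- function(daily, year) {
  fall <- .window_days(daily, as.Date(sprintf("%d-08-01", year - 1)),
                       as.Date(sprintf("%d-12-31", year - 1)))
  spr <- .window_days(daily, as.Date(sprintf("%d-01-01", year)),
                      as.Date(sprintf("%d-06-30", year)))
  f_dates <- fall$date[!is.na(fall$tmin) & fall$tmin <= 0]
  s_dates <- spr$date[!is.na(spr$tmin) & spr$tmin <= 0]
  ff <- if (length(f_dates)) min(f_dates) else as.Date(NA)
  ls <- if (length(s_dates)) max(s_dates) else as.Date(NA)
  c(first_fall_freeze = if (is.na(ff)) NA_real_ else
      as.numeric(format(ff, "%j")),
    last_spring_freeze = if (is.na(ls)) NA_real_ else
      as.numeric(format(ls, "%j")),
    winter_duration = if (is.na(ff) || is.na(ls)) NA_real_ else
      as.numeric(ls - ff))
}

#' Timber-stand areas by age class
#'
#' Bins harvested stands into elk-habitat age classes as of a query year:
#' clear-cut (age < 1 year), early regeneration (1-5), late regeneration
#' (6-30), and mature (> 30 years since harvest).
#'
#' @param stands data frame with columns \code{harvest_year} and \code{area}
#'   (km^2, positive).
#' @param year query year; all harvest years must be <= \code{year}.
#' @return named numeric vector \code{timber_lt1}, \code{timber_1_5},
#'   \code{timber_6_30}, \code{timber_gt30}, \code{timber_total} (km^2).
#' @export
timber_age_class_areas <- function(stands, year) {
  if (nrow(stands) == 0) {
    return(c(timber_lt1 = 0, timber_1_5 = 0, timber_6_30 = 0,
             timber_gt30 = 0, timber_total = 0))
  }
  stopifnot(all(stands$area > 0))
  age <- year - stands$harvest_year
  if (any(age < 0)) stop("stand harvested after query year ", year)
  cls <- cut(age, breaks = c(-0.5, 0.5, 5.5, 30.5, Inf),
             labels = c("timber_lt1", "timber_1_5", "timber_6_30",
                        "timber_gt30"))
  out <- tapply(stands$area, cls, sum)
  out[is.na(out)] <- 0
  c(out, timber_total = sum(stands$area))
}

#' Assemble the predictor table
#'
#' Builds one row per response year containing every seasonal, freeze,
#' drought, timber, and predator-abundance predictor, applying the
#' carryover-lag convention exactly once per lagged predictor.
#'
#' @inheritParams derive_seasonal_metrics
#' @param years integer vector of response years.
#' @param stands optional stand table (see
#'   \code{\link{timber_age_class_areas}}); areas are evaluated in year
#'   \code{t - 1}.
#' @param bear optional data frame \code{year}, \code{abundance} of
#'   reconstructed predator abundance, matched to year \code{t}.
#' @param latitude station latitude in degrees, for potential
#'   evapotranspiration (default 57.75, Kodiak).
#' @param spei6_window window convention for the forest drought index ending
#'   in July: \code{"feb_jul"} (6-month scale, default) or \code{"jan_jul"}
#'   (7-month scale).
#' @param spei_calibration two-element integer vector of first and last
#'   calibration years for the drought-index fit.
#' @return data frame, one row per year, with a \code{"scaling"}-free raw
#'   predictor set (standardize with \code{\link{standardize_predictors}}).
#' @export
build_predictor_table <- function(daily, years, stands = NULL, bear = NULL,
                                  latitude = 57.75,
                                  spei6_window = c("feb_jul", "jan_jul"),
                                  spei_calibration = NULL,
                                  max_missing = 0.1) {
  spei6_window <- match.arg(spei6_window)
  seas <- t(vapply(years, function(y)
    derive_seasonal_metrics(daily, y, max_missing = max_missing),
    numeric(11)))
  frz <- t(vapply(years, function(y) freeze_metrics(daily, y), numeric(3)))
  tab <- data.frame(year = years, seas, frz)

  # drought indices, computed on the full monthly series then lagged
  mon <- monthly_climate(daily, max_missing = max_missing)
  if (nrow(mon) >= 24 * 12 / 12) {
    mon$pet <- thornthwaite_pet(mon$tmean, latitude, mon$month)
    mon$balance <- mon$precip - mon$pet
    calib <- if (is.null(spei_calibration))
      range(mon$year) else spei_calibration
    k6 <- if (spei6_window == "feb_jul") 6L else 7L
    sp6 <- try(spei_index(mon$balance, mon$year, mon$month, scale_k = k6,
                          calibration = calib), silent = TRUE)
    sp3 <- try(spei_index(mon$balance, mon$year, mon$month, scale_k = 3L,
                          calibration = calib), silent = TRUE)
    if (!inherits(sp6, "try-error")) {
      tab$spei_forest <- sp6[match(paste(years - 1L, 7L),
                                   paste(mon$year, mon$month))]
    } else tab$spei_forest <- NA_real_
    if (!inherits(sp3, "try-error")) {
      tab$spei_grassland <- sp3[match(paste(years - 1L, 9L),
                                      paste(mon$year, mon$month))]
    } else tab$spei_grassland <- NA_real_
  } else {
    tab$spei_forest <- tab$spei_grassland <- NA_real_
  }

  if (!is.null(stands)) {
    # stands harvested after a given response year do not yet exist for it
    tmb <- t(vapply(years, function(y)
      timber_age_class_areas(stands[stands$harvest_year <= y - 1L, ,
                                    drop = FALSE], y - 1L),
      numeric(5)))
    tab <- cbind(tab, tmb)
  }
  if (!is.null(bear)) {
    tab$bear_abundance <- bear$abundance[match(years, bear$year)]
  }
  rownames(tab) <- NULL
  tab
}

#' Monthly climate aggregates from a daily series
#'
#' @inheritParams derive_seasonal_metrics
#' @return data frame \code{year}, \code{month}, \code{tmean} (deg C),
#'   \code{precip} (mm total); months with too many missing days are
#'   \code{NA}.
#' @export
monthly_climate <- function(daily, max_missing = 0.1) {
  ym <- format(daily$date, "%Y-%m")
  key <- sort(unique(ym))
  yr <- as.integer(substr(key, 1, 4))
  mo <- as.integer(substr(key, 6, 7))
  exp_days <- vapply(seq_along(key), function(i) {
    first <- as.Date(sprintf("%d-%02d-01", yr[i], mo[i]))
    as.numeric(seq(first, by = "month", length.out = 2)[2] - first)
  }, numeric(1))
  tm <- vapply(seq_along(key), function(i) {
    x <- daily$tmean[ym == key[i]]
    .window_mean(x, exp_days[i], max_missing)
  }, numeric(1))
  pr <- vapply(seq_along(key), function(i) {
    x <- daily$precip[ym == key[i]]
    .window_sum(x, exp_days[i], max_missing)
  }, numeric(1))
  data.frame(year = yr, month = mo, tmean = tm, precip = pr)
}
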