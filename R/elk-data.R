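# Composition-count filtering and aggregation, count-series interpolation,
# predictor standardization, and long-term linear trends.

#' Filter herd composition counts
#'
#' Applies the data-quality rules used before pooling herd counts into age
#' ratios: records are dropped when calves exceed cows (recording error or
#' incomplete group count), when zero calves were counted (survey too late
#' to distinguish calves), when adults were not separated into cows and
#' bulls, or when the herd is blocklisted.  After record-level filtering,
#' any year whose summed group total (cows + calves + bulls) is at or below
#' \code{min_group_total} is dropped entirely.
#'
#' @param records data frame with columns \code{year}, \code{herd},
#'   \code{cows}, \code{calves}, \code{bulls}; \code{NA} cows or bulls mean
#'   adults were not counted separately.
#' @param herds optional character vector restricting to a herd group.
#' @param min_group_total small-count threshold (default 5); set to
#'   \code{-Inf} to disable.
#' @param blocklist herds excluded outright (e.g. where canopy cover
#'   precludes accurate counts); default none.
#' @return list with \code{retained} (data frame) and \code{excluded}
#'   (data frame with a \code{reason} column).
#' @export
filter_composition_counts <- function(records, herds = NULL,
                                      min_group_total = 5,
                                      blocklist = character(0)) {
  rec <- records
  if (!is.null(herds)) rec <- rec[rec$herd %in% herds, , drop = FALSE]
  reason <- rep(NA_character_, nrow(rec))
  reason[rec$herd %in% blocklist] <- "herd_blocklisted"
  unk <- is.na(reason) &
    (is.na(rec$cows) | is.na(rec$bulls) | is.na(rec$calves))
  reason[unk] <- "adults_unknown"
  zc <- is.na(reason) & !is.na(rec$calves) & rec$calves == 0
  reason[zc] <- "zero_calves"
  ce <- is.na(reason) & !is.na(rec$calves) & !is.na(rec$cows) &
    rec$calves > rec$cows
  reason[ce] <- "calves_exceed_cows"

  keep <- is.na(reason)
  retained <- rec[keep, , drop = FALSE]
  # small-count rule on the summed group total per year
  tot <- tapply(retained$cows + retained$calves + retained$bulls,
                retained$year, sum)
  small_years <- as.integer(names(tot))[!is.na(tot) & tot <= min_group_total]
  small <- retained$year %in% small_years
  excluded <- rbind(
    cbind(rec[!keep, , drop = FALSE], reason = reason[!keep]),
    cbind(retained[small, , drop = FALSE],
          reason = rep("group_total_below_threshold", sum(small))))
  retained <- retained[!small, , drop = FALSE]
  rownames(retained) <- rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded)
}

#' Pooled age ratios (calves per 100 adult females)
#'
#' Sums calves and cows across the herds of a group within each year, then
#' forms 100 * calves / cows.  This is a pooled ratio, not a mean of
#' per-herd ratios.
#'
#' @param records filtered composition counts (see
#'   \code{\link{filter_composition_counts}}).
#' @param herds optional herd subset.
#' @param label group label stored on the result.
#' @return data frame \code{year}, \code{ratio}, \code{n_herds}, with
#'   attribute \code{"group"}; years whose pooled cow count is zero are
#'   omitted.
#' @export
aggregate_age_ratios <- function(records, herds = NULL, label = "all") {
  rec <- records
  if (!is.null(herds)) rec <- rec[rec$herd %in% herds, , drop = FALSE]
  if (nrow(rec) == 0)
    return(structure(data.frame(year = integer(0), ratio = numeric(0),
                                n_herds = integer(0)), group = label))
  cows <- tapply(rec$cows, rec$year, sum)
  calves <- tapply(rec$calves, rec$year, sum)
  nh <- tapply(rec$herd, rec$year, function(h) length(unique(h)))
  ok <- cows > 0
  if (any(!ok))
    warning("omitting years with zero pooled cows: ",
            paste(names(cows)[!ok], collapse = ", "), call. = FALSE)
  out <- data.frame(year = as.integer(names(cows))[ok],
                    ratio = 100 * as.numeric(calves[ok] / cows[ok]),
                    n_herds = as.integer(nh[ok]))
  rownames(out) <- NULL
  structure(out, group = label)
}

#' Linearly interpolate missing September counts
#'
#' Fills interior missing years of a count series by linear interpolation
#' between the nearest observed neighbours; leading or trailing gaps are an
#' error.
#'
#' @param series data frame with columns \code{year} and \code{count}
#'   (\code{NA} for missing years; absent years are treated as missing).
#' @return data frame \code{year}, \code{count}, \code{imputed} (logical)
#'   covering every year in the span.
#' @export
interpolate_missing_counts <- function(series) {
  yrs <- seq(min(series$year), max(series$year))
  cnt <- series$count[match(yrs, series$year)]
  if (is.na(cnt[1]) || is.na(cnt[length(cnt)]))
    stop("first and last years must be observed")
  filled <- stats::approx(yrs[!is.na(cnt)], cnt[!is.na(cnt)], xout = yrs)$y
  data.frame(year = yrs, count = filled, imputed = is.na(cnt))
}

#' Standardize predictor columns
#'
#' Centres and scales each predictor by its sample mean and standard
#' deviation over the supplied rows (the years entering the model), storing
#' the scaling for back-transformation.
#'
#' @param table predictor data frame (a \code{year} column, if present, is
#'   left untouched).
#' @param cols columns to standardize; default all numeric except
#'   \code{year}.
#' @return the table with standardized columns and attribute
#'   \code{"scaling"}: data frame \code{predictor}, \code{mean}, \code{sd}.
#' @export
standardize_predictors <- function(table, cols = NULL) {
  if (is.null(cols))
    cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                    "year")
  sc <- data.frame(predictor = cols, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(cols)) {
    x <- table[[cols[i]]]
    m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("constant or empty predictor column: ", cols[i])
    table[[cols[i]]] <- (x - m) / s
    sc$mean[i] <- m; sc$sd[i] <- s
  }
  attr(table, "scaling") <- sc
  table
}

#' Long-term linear trend
#'
#' Ordinary least squares of a series on calendar year, with the two-sided
#' t-test on the slope.
#'
#' @param year,value numeric vectors (or a two-column data frame as first
#'   argument).
#' @return list \code{slope}, \code{intercept}, \code{r.squared}, \code{t},
#'   \code{p}, \code{n}.
#' @export
linear_trend <- function(year, value = NULL) {
  if (is.null(value)) { value <- year[[2]]; year <- year[[1]] }
  ok <- is.finite(year) & is.finite(value)
  year <- year[ok]; value <- value[ok]
  if (length(year) < 3) stop("need at least 3 points for a trend")
  fit <- stats::lm(value ~ year)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r.squared = s$r.squared, t = s$coefficients[2, "t value"],
       p = s$coefficients[2, "Pr(>|t|)"], n = length(year))
}
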