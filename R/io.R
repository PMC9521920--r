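# Delimited-text readers and writers for the standard input layouts:
# daily weather (GHCN-Daily-style column names accepted), bear mortality /
# harvest-at-age tables, elk composition counts, and count + harvest
# series.  All files are plain CSV with a header; missing values are empty
# fields or NA.

.ghcn_map <- c(DATE = "date", TMIN = "tmin", TMAX = "tmax", TAVG = "tmean",
               PRCP = "precip", SNOW = "snowfall", SNWD = "snow_depth")

#' Read a daily weather table
#'
#' @param path CSV file with ISO-8601 dates; canonical column names
#'   (\code{date}, \code{tmin}, \code{tmax}, \code{tmean}, \code{precip},
#'   \code{snowfall}, \code{snow_depth}) or GHCN-Daily names (\code{DATE},
#'   \code{TMIN}, ...) are accepted.  Units are deg C and mm.
#' @param col_map optional named character vector mapping file columns to
#'   canonical names, overriding the defaults.
#' @return data frame in canonical layout; \code{tmean} is filled from
#'   \code{(tmin + tmax) / 2} when absent.
#' @export
read_daily_weather <- function(path, col_map = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  map <- c(.ghcn_map, col_map)
  hit <- names(d) %in% names(map)
  names(d)[hit] <- map[names(d)[hit]]
  stopifnot("date" %in% names(d))
  d$date <- as.Date(d$date)
  for (v in c("tmin", "tmax", "tmean", "precip", "snowfall", "snow_depth"))
    if (!v %in% names(d)) d[[v]] <- NA_real_
  if (all(is.na(d$tmean))) d$tmean <- (d$tmin + d$tmax) / 2
  bad <- !is.na(d$tmin) & !is.na(d$tmax) & d$tmin > d$tmax
  if (any(bad)) stop("tmin > tmax on ", sum(bad), " days")
  d[, c("date", "tmin", "tmax", "tmean", "precip", "snowfall",
        "snow_depth")]
}

#' Read bear mortality records or a pre-binned harvest-at-age table
#'
#' Accepts either per-animal records (columns \code{year}, \code{age}) or a
#' pre-binned layout (columns \code{year}, \code{class1..classM},
#' \code{prop_aged}); the latter is scaled by the aged proportion to a
#' \code{harvest_at_age} object directly.
#'
#' @param path CSV file.
#' @return data frame of records, or a \code{harvest_at_age} object for the
#'   pre-binned layout.
#' @export
read_bear_mortality <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("age" %in% names(d)) return(d[, c("year", "age")])
  cls <- grep("^class[0-9]+$", names(d), value = TRUE)
  stopifnot(length(cls) >= 3, "year" %in% names(d))
  S <- as.matrix(d[, cls])
  rownames(S) <- d$year
  pa <- if ("prop_aged" %in% names(d)) d$prop_aged else rep(1, nrow(d))
  H <- S / ifelse(pa > 0, pa, 1)
  total <- if ("total" %in% names(d)) d$total else rowSums(H)
  structure(list(year = d$year, counts = H, total = total,
                 prop_aged = pa, aged_counts = S,
                 class_breaks = seq_len(length(cls)) - 1L,
                 log = character(0)),
            class = "harvest_at_age")
}

#' Read elk composition counts
#'
#' @param path CSV with columns \code{year}, \code{herd}, \code{cows},
#'   \code{calves}, \code{bulls}.
#' @return data frame.
#' @export
read_composition_counts <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("year", "herd", "cows", "calves", "bulls") %in% names(d)))
  d
}

#' Read a count-plus-harvest series
#'
#' @param path CSV with columns \code{year}, \code{count}, and optionally
#'   \code{harvest}.
#' @return data frame.
#' @export
read_count_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("year", "count") %in% names(d)))
  if (!"harvest" %in% names(d)) d$harvest <- 0
  d
}

#' Write a table as CSV with empty fields for missing values
#'
#' @param x data frame.
#' @param path output file.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}
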