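# Downing cohort reconstruction of predator abundance from harvest-at-age
# (known-mortality) data.  Age-class convention: classes 1..m-1 are
# single-year ages 0..m-2 and class m is open-ended (ages >= m-1), so the
# cohort recursion N[i,t] = H[i,t] + N[i+1,t+1] is well defined and the two
# oldest classes are closed by the equal-harvest-mortality-rate assumption.

#' Build a harvest-at-age matrix from mortality records
#'
#' Bins aged mortalities into \code{n_classes} age classes and allocates
#' each year's un-aged mortalities across classes so that row totals equal
#' total known mortalities.  The default allocation is proportional to the
#' year's aged class distribution (equivalently, dividing aged counts by the
#' proportion aged).
#'
#' @param records data frame with columns \code{year}, \code{age}
#'   (\code{NA} for mortalities that were not aged).
#' @param n_classes number of age classes m (default 5).
#' @param class_breaks increasing integer ages opening each class; default
#'   \code{0:(n_classes - 1)}, i.e. single-year classes with an open oldest
#'   class.
#' @param unaged how to allocate years with mortalities but no aged animals:
#'   \code{"error"} (default) or \code{"uniform"} (spread evenly, logged).
#' @return object of class \code{harvest_at_age}: list with \code{year},
#'   matrix \code{counts} (years x classes, allocated), \code{total}
#'   (known mortalities), \code{prop_aged}, and \code{log} (character).
#' @export
build_harvest_matrix <- function(records, n_classes = 5L,
                                 class_breaks = NULL,
                                 unaged = c("error", "uniform")) {
  unaged <- match.arg(unaged)
  if (is.null(class_breaks)) class_breaks <- 0:(n_classes - 1L)
  stopifnot(length(class_breaks) == n_classes,
            all(diff(class_breaks) > 0))
  aged <- records[!is.na(records$age), , drop = FALSE]
  if (any(aged$age < 0 | aged$age != floor(aged$age)))
    stop("ages must be non-negative integers")
  years <- sort(unique(records$year))
  m <- n_classes
  cls <- findInterval(aged$age, class_breaks)
  S <- matrix(0, length(years), m,
              dimnames = list(years, paste0("class", 1:m)))
  for (i in seq_len(nrow(aged)))
    S[as.character(aged$year[i]), cls[i]] <- S[as.character(aged$year[i]), cls[i]] + 1
  total <- as.numeric(table(factor(records$year, levels = years)))
  n_aged <- rowSums(S)
  log_lines <- character(0)
  H <- S
  for (r in seq_along(years)) {
    if (total[r] == 0) next
    if (n_aged[r] == 0) {
      if (unaged == "error")
        stop("year ", years[r], " has mortalities but no aged animals")
      H[r, ] <- total[r] / m
      log_lines <- c(log_lines, sprintf(
        "year %d: %d un-aged mortalities allocated uniformly",
        years[r], total[r]))
    } else {
      H[r, ] <- S[r, ] * total[r] / n_aged[r]
    }
  }
  structure(list(year = years, counts = H, total = total,
                 prop_aged = ifelse(total > 0, n_aged / total, NA_real_),
                 aged_counts = S, class_breaks = class_breaks,
                 log = log_lines),
            class = "harvest_at_age")
}

#' Collapse a years-by-age harvest matrix into age classes
#'
#' @param H numeric matrix, years in rows (rownames = years), single-year
#'   ages 0, 1, ... in columns.
#' @param class_breaks increasing integer ages opening each class.
#' @return years x classes matrix suitable for
#'   \code{\link{downing_reconstruct}}.
#' @export
collapse_age_classes <- function(H, class_breaks = 0:4) {
  ages <- as.integer(colnames(H))
  cls <- findInterval(ages, class_breaks)
  m <- length(class_breaks)
  out <- sapply(1:m, function(i)
    rowSums(H[, cls == i, drop = FALSE]))
  dimnames(out) <- list(rownames(H), paste0("class", 1:m))
  out
}

#' @export
print.harvest_at_age <- function(x, ...) {
  cat("Harvest-at-age table:", length(x$year), "years,",
      ncol(x$counts), "age classes\n")
  cat("Total known mortalities:", sum(x$total),
      sprintf("(aggregate aged fraction %.3f)\n",
              sum(x$aged_counts) / sum(x$total)))
  invisible(x)
}

#' Downing population reconstruction
#'
#' Reconstructs minimum population size backward in time from a
#' harvest-at-age matrix.  Classes below the oldest two follow the cohort
#' recursion \code{N[i,t] = H[i,t] + N[i+1,t+1]}.  The two oldest classes
#' are closed, per year, by assuming equal harvest-mortality rates:
#' \code{H[m-1,t]/N[m-1,t] = H[m,t]/N[m,t]} together with the harvest-only
#' balance \code{N[m-1,t] + N[m,t] = H[m-1,t] + H[m,t] + N[m,t+1]}.  The
#' terminal year is initialised at the minimum-alive value (that year's
#' harvest), and the final \code{m - 1} data years -- where future cohort
#' harvests are unobserved -- are dropped from the output.
#'
#' @param H a \code{harvest_at_age} object (see
#'   \code{\link{build_harvest_matrix}}) or a plain years x classes matrix
#'   with rownames giving years.
#' @param closure \code{"equal_rate"} (default) or \code{"minimum_alive"}
#'   (oldest two classes set to their own harvests plus survivors).
#' @return object of class \code{downing_recon}: list with \code{year}
#'   (retained years), \code{N} (years x classes matrix), \code{total}
#'   (reconstructed N_t), \code{truncated} (dropped years), \code{log}.
#' @export
downing_reconstruct <- function(H, closure = c("equal_rate",
                                               "minimum_alive")) {
  closure <- match.arg(closure)
  if (inherits(H, "harvest_at_age")) {
    years <- H$year; Hm <- H$counts
  } else {
    Hm <- as.matrix(H); years <- as.integer(rownames(Hm))
  }
  m <- ncol(Hm)
  T_ <- nrow(Hm)
  if (T_ < m + 1) stop("need at least m + 1 consecutive years of data")
  if (any(diff(years) != 1)) stop("years must be consecutive")
  if (sum(Hm) == 0) stop("empty harvest table: nothing to reconstruct")
  N <- matrix(0, T_, m, dimnames = dimnames(Hm))
  log_lines <- character(0)
  N[T_, ] <- Hm[T_, ]
  for (t in (T_ - 1):1) {
    for (i in 1:(m - 2)) N[t, i] <- Hm[t, i] + N[t + 1, i + 1]
    h1 <- Hm[t, m - 1]; h2 <- Hm[t, m]
    S <- N[t + 1, m]
    if (closure == "minimum_alive" || h1 + h2 == 0) {
      # no rate information: place survivors in the open class
      N[t, m - 1] <- h1
      N[t, m] <- h2 + S
      if (closure == "equal_rate" && h1 + h2 == 0 && S > 0)
        log_lines <- c(log_lines, sprintf(
          "year %d: no harvest in oldest two classes; minimum-alive fallback",
          years[t]))
    } else if (h1 == 0) {
      N[t, m - 1] <- 0
      N[t, m] <- h2 + S
      log_lines <- c(log_lines, sprintf(
        "year %d: zero class-%d harvest; minimum-alive fallback",
        years[t], m - 1))
    } else {
      pool <- h1 + h2 + S
      N[t, m - 1] <- h1 * pool / (h1 + h2)
      N[t, m] <- h2 * pool / (h1 + h2)
    }
  }
  keep <- 1:(T_ - (m - 1))
  structure(list(year = years[keep], N = N[keep, , drop = FALSE],
                 total = rowSums(N[keep, , drop = FALSE]),
                 truncated = years[-keep], closure = closure,
                 log = log_lines),
            class = "downing_recon")
}

#' @export
print.downing_recon <- function(x, ...) {
  cat("Downing population reconstruction (", x$closure, " closure)\n",
      sep = "")
  cat("Years ", min(x$year), "-", max(x$year), "; dropped ",
      length(x$truncated), " terminal years (",
      paste(x$truncated, collapse = ", "), ")\n", sep = "")
  cat(sprintf("Reconstructed abundance: mean %.1f, range %.0f-%.0f\n",
              mean(x$total), min(x$total), max(x$total)))
  invisible(x)
}

#' @export
summary.downing_recon <- function(object, ...) {
  data.frame(year = object$year, round(object$N, 2),
             total = round(object$total, 2))
}

#' @export
plot.downing_recon <- function(x, ...) {
  plot(x$year, x$total, type = "b", pch = 16, xlab = "Year",
       ylab = "Reconstructed abundance", ...)
  invisible(x)
}
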