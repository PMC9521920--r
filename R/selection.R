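# Two-stage hypothesis-representative predictor selection: a univariate R^2
# screen within each hypothesis, then collinearity resolution at |r| > 0.7
# by exhaustive search over candidate combinations, maximizing first the
# number of hypotheses retained and then the total R^2 of the chosen set.

#' Univariate R^2 screen
#'
#' Fits one ordinary least-squares regression of the response on each
#' candidate predictor over their overlapping years and reports R^2.
#'
#' @param response data frame \code{year}, \code{value} (or named vector of
#'   values with years as names).
#' @param predictors data frame with a \code{year} column and one column per
#'   candidate.
#' @param min_overlap minimum complete-case years per predictor (default 3).
#' @return data frame \code{predictor}, \code{r.squared}, \code{n};
#'   predictors with insufficient overlap are reported with \code{NA} R^2.
#' @export
univariate_r2_screen <- function(response, predictors, min_overlap = 3) {
  if (!is.data.frame(response))
    response <- data.frame(year = as.integer(names(response)),
                           value = as.numeric(response))
  cand <- setdiff(names(predictors), "year")
  out <- data.frame(predictor = cand, r.squared = NA_real_, n = 0L)
  y_all <- response$value[match(predictors$year, response$year)]
  for (i in seq_along(cand)) {
    x <- predictors[[cand[i]]]
    ok <- is.finite(x) & is.finite(y_all)
    out$n[i] <- sum(ok)
    if (sum(ok) < min_overlap) next
    out$r.squared[i] <- summary(stats::lm(y_all[ok] ~ x[ok]))$r.squared
  }
  out
}

#' Select hypothesis-representative predictors
#'
#' Given the R^2 screen, a mapping of hypotheses to their candidate
#' predictors, and the candidate correlation matrix, chooses one predictor
#' per hypothesis such that no chosen pair is correlated beyond
#' \code{threshold}.  The search is exhaustive over one-candidate-per-
#' hypothesis combinations (plus dropping a hypothesis whose candidates are
#' exhausted), maximizing first the number of hypotheses retained, then the
#' summed R^2, breaking remaining ties lexicographically on predictor names.
#'
#' @param r2 data frame from \code{\link{univariate_r2_screen}}.
#' @param hypotheses named list: hypothesis -> character vector of candidate
#'   predictor names (each candidate in exactly one hypothesis).
#' @param corr symmetric correlation matrix covering all candidates
#'   (dimnames required).
#' @param threshold absolute-correlation conflict threshold (default 0.7).
#' @param max_candidates per-hypothesis cap on candidates entering the
#'   exhaustive search, taken in decreasing R^2 order (default 6).
#' @return list of class \code{predictor_selection}: \code{chosen} (named
#'   character: hypothesis -> predictor; dropped hypotheses absent),
#'   \code{r2}, \code{substitutions} (log of hypotheses whose top candidate
#'   was displaced), \code{dropped}.
#' @export
select_representatives <- function(r2, hypotheses, corr, threshold = 0.7,
                                   max_candidates = 6L) {
  all_cand <- unlist(hypotheses, use.names = FALSE)
  if (anyDuplicated(all_cand))
    stop("a candidate appears in more than one hypothesis")
  stopifnot(all(all_cand %in% rownames(corr)),
            all(all_cand %in% r2$predictor))
  r2v <- stats::setNames(r2$r.squared, r2$predictor)

  ranked <- lapply(hypotheses, function(cand) {
    v <- r2v[cand]
    cand <- cand[is.finite(v)]
    v <- v[is.finite(v)]
    cand[order(-v, cand)][seq_len(min(length(cand), max_candidates))]
  })
  hyps <- names(ranked)

  # options per hypothesis: each candidate, or NA meaning "drop"
  opts <- lapply(ranked, function(cand) c(cand, NA_character_))
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  names(grid) <- hyps

  best <- NULL; best_key <- NULL
  for (row in seq_len(nrow(grid))) {
    sel <- unlist(grid[row, ], use.names = TRUE)
    sel <- sel[!is.na(sel)]
    if (length(sel) > 1) {
      cm <- abs(corr[sel, sel, drop = FALSE])
      diag(cm) <- 0
      if (max(cm) > threshold) next
    }
    key <- list(n = length(sel), r2 = sum(r2v[sel]),
                lex = paste(sort(sel), collapse = "|"))
    if (is.null(best) ||
        key$n > best_key$n ||
        (key$n == best_key$n && key$r2 > best_key$r2 + 1e-12) ||
        (key$n == best_key$n && abs(key$r2 - best_key$r2) <= 1e-12 &&
         key$lex < best_key$lex)) {
      best <- sel; best_key <- key
    }
  }
  if (is.null(best)) stop("no conflict-free selection exists")

  subs <- character(0)
  for (h in hyps) {
    top <- ranked[[h]][1]
    if (!h %in% names(best)) {
      subs <- c(subs, sprintf("%s: dropped (candidates exhausted)", h))
    } else if (!identical(unname(best[h]), unname(top))) {
      subs <- c(subs, sprintf(
        "%s: top candidate '%s' conflicted; substituted '%s'",
        h, top, best[h]))
    }
  }
  structure(list(chosen = best, r2 = r2,
                 substitutions = subs,
                 dropped = setdiff(hyps, names(best)),
                 threshold = threshold),
            class = "predictor_selection")
}

#' @export
print.predictor_selection <- function(x, ...) {
  cat("Hypothesis-representative predictors (|r| <=", x$threshold, "):\n")
  for (h in names(x$chosen)) cat("  ", h, "->", x$chosen[h], "\n")
  if (length(x$substitutions))
    cat("Substitutions:\n", paste(" ", x$substitutions, collapse = "\n"),
        "\n")
  if (length(x$dropped))
    cat("Dropped hypotheses:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
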