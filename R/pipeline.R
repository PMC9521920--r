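# End-to-end orchestration: covariate construction -> predator
# reconstruction -> elk data preparation -> predictor selection -> three
# recruitment models (timber, non-timber, island-wide; the timber covariate
# enters only the timber and island-wide models) -> Gompertz state-space
# abundance model -> density-dependence test.  Every random stage derives
# its seed deterministically from the run seed.

#' Default hypothesis-to-candidate map
#'
#' Groups every predictor-table column under the hypothesis it represents:
#' winter severity, spring bottleneck, maternal carryover, predation, and
#' timber harvest.
#'
#' @return named list of character vectors.
#' @export
default_hypothesis_map <- function() {
  list(
    winter_severity = c("mean_winter_temp", "mean_monthly_min_winter_temp",
                        "total_snowfall", "mean_snow_depth"),
    spring_bottleneck = c("mean_spring_temp", "spring_precip",
                          "last_spring_freeze", "winter_duration"),
    maternal_carryover = c("mean_summer_temp", "summer_precip", "gdd",
                           "spei_forest", "spei_grassland",
                           "mean_fall_temp", "fall_precip",
                           "first_fall_freeze"),
    predation = "bear_abundance",
    timber_harvest = c("timber_lt1", "timber_1_5", "timber_6_30",
                       "timber_gt30", "timber_total"))
}

#' Default run configuration (synthetic inputs)
#'
#' @param seed run seed.
#' @param years response years of the count series (default 1958:2020).
#' @param mcmc MCMC settings (default \code{\link{mcmc_config}}).
#' @param n_boot bootstrap replicates for the density-dependence test.
#' @return configuration list accepted by \code{\link{run_pipeline}}.
#' @export
default_run_config <- function(seed = 1L, years = 1958:2020,
                               mcmc = mcmc_config(seed = seed),
                               n_boot = 2000L) {
  list(
    seed = as.integer(seed),
    years = years,
    ratio_years = 1967:2013,
    synthetic = list(
      weather = list(mean_temp = 4, amplitude = 7.5, noise_sd = 2.5),
      bear = list(n_years = 51, n0 = 90, recruit_rate = 0.19,
                  survival = 0.93, harvest_rate = 0.1,
                  aged_fraction = 0.92, start_year = 1967),
      elk = list(a = 1.45, b = -0.27, sigma_proc = 0.23, sigma_obs = 0.20,
                 n1 = 100, harvest_frac = 0.1,
                 c_cov = c(mean_winter_temp = 0.14),
                 beta = c(intercept = 33, first_fall_freeze = 2.8,
                          bear_abundance = -3.4),
                 resid_sd = 7),
      herds = list(timber = c("MarkaLake", "Waterfall", "PortageLake",
                              "DuckMountain", "SealBay"),
                   non_timber = c("Raspberry", "Malina"))),
    inputs = NULL,                      # or list of file paths
    hypotheses = default_hypothesis_map(),
    thresholds = list(correlation = 0.7, rhat = 1.1, cri = 0.95,
                      trend_alpha = 0.05),
    n_boot = as.integer(n_boot),
    mcmc = mcmc)
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_run_config()
  mod <- function(b, c) {
    for (n in names(c)) {
      b[[n]] <- if (is.list(c[[n]]) && is.list(b[[n]])) mod(b[[n]], c[[n]])
                else c[[n]]
    }
    b
  }
  if (!is.null(config)) base <- mod(base, config)
  base
}

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic inputs (default) or supplied files,
#' writing screening, model-summary, trend, and exclusion tables plus a
#' machine-readable manifest to \code{out_dir}.
#'
#' @param config configuration list (see \code{\link{default_run_config}})
#'   or path to a YAML file with overrides; \code{NULL} for defaults.
#' @param out_dir output directory (created if missing); \code{NULL} skips
#'   writing.
#' @param quiet suppress stage messages.
#' @return invisible list with every stage result: \code{predictors},
#'   \code{bear}, \code{ratios}, \code{trends}, \code{screen},
#'   \code{selection}, \code{recruitment} (list of three fits),
#'   \code{abundance}, \code{ddtest}, \code{exclusions}, \code{manifest}.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, quiet = FALSE) {
  cfg <- .load_config(config)
  seed <- cfg$seed
  say <- function(...) if (!quiet) message("[elkdyn] ", ...)
  yrs <- cfg$years
  ryrs <- cfg$ratio_years

  # --- inputs ------------------------------------------------------------
  if (is.null(cfg$inputs)) {
    say("simulating inputs (seed ", seed, ")")
    weather <- do.call(simulate_daily_weather,
                       c(list(years = (min(yrs) - 2):max(yrs),
                              seed = seed + 11L), cfg$synthetic$weather))
    bear_sim <- do.call(simulate_bear_harvest,
                        c(list(seed = seed + 12L), cfg$synthetic$bear))
    bear_records <- bear_sim$records
    stands <- simulate_timber_stands(1976:max(yrs), seed = seed + 13L)
    comp <- NULL; counts_in <- NULL   # built after covariates
  } else {
    say("reading inputs")
    weather <- read_daily_weather(cfg$inputs$weather)
    bear_records <- read_bear_mortality(cfg$inputs$bear)
    stands <- if (!is.null(cfg$inputs$stands))
      utils::read.csv(cfg$inputs$stands) else NULL
    comp <- read_composition_counts(cfg$inputs$composition)
    counts_in <- read_count_series(cfg$inputs$counts)
  }

  # --- bear reconstruction ----------------------------------------------
  say("Downing reconstruction")
  H <- if (inherits(bear_records, "harvest_at_age")) bear_records
       else build_harvest_matrix(bear_records)
  recon <- downing_reconstruct(H)
  bear_series <- data.frame(year = recon$year, abundance = recon$total)

  # --- covariates ---------------------------------------------------------
  say("building predictor table")
  predictors <- build_predictor_table(weather, years = yrs, stands = stands,
                                      bear = bear_series)

  # --- elk data ------------------------------------------------------------
  herds <- cfg$synthetic$herds
  if (is.null(cfg$inputs)) {
    elk_cfg <- cfg$synthetic$elk
    cnt_cols <- names(elk_cfg$c_cov)
    rat_cols <- setdiff(names(elk_cfg$beta), "intercept")
    cov_cnt <- standardize_predictors(
      predictors[, c("year", cnt_cols), drop = FALSE], cols = cnt_cols)
    rat_tab <- predictors[, c("year", rat_cols), drop = FALSE]
    rat_tab <- rat_tab[stats::complete.cases(rat_tab) &
                         rat_tab$year %in% ryrs, , drop = FALSE]
    cov_rat <- standardize_predictors(rat_tab, cols = rat_cols)
    elk_sim <- do.call(simulate_elk_system,
                       c(list(years = yrs, seed = seed + 14L,
                              covariates = cov_cnt,
                              ratio_years = cov_rat$year,
                              ratio_covariates = cov_rat),
                         elk_cfg))
    counts_in <- elk_sim$counts
    comp <- simulate_composition_counts(
      elk_sim$ratios, herds = c(herds$timber, herds$non_timber),
      seed = seed + 15L)
  }

  say("filtering composition counts")
  flt_t <- filter_composition_counts(comp, herds = herds$timber)
  flt_n <- filter_composition_counts(comp, herds = herds$non_timber,
                                     min_group_total = -Inf)
  flt_i <- filter_composition_counts(comp, min_group_total = -Inf,
                                     blocklist = "Tonki")
  ratios <- list(
    timber = aggregate_age_ratios(flt_t$retained, label = "timber"),
    non_timber = aggregate_age_ratios(flt_n$retained, label = "non-timber"),
    island_wide = aggregate_age_ratios(flt_i$retained,
                                       label = "island-wide"))

  counts <- interpolate_missing_counts(counts_in[, c("year", "count")])
  harvest <- data.frame(year = counts_in$year,
                        harvest = counts_in$harvest)

  # --- trends --------------------------------------------------------------
  say("trend fits")
  trends <- rbind(
    data.frame(series = "bear_abundance",
               as.data.frame(linear_trend(bear_series$year,
                                          bear_series$abundance))),
    data.frame(series = "counts",
               as.data.frame(linear_trend(counts$year, counts$count))),
    do.call(rbind, lapply(names(ratios), function(g)
      data.frame(series = paste0("ratio_", g),
                 as.data.frame(linear_trend(ratios[[g]]$year,
                                            ratios[[g]]$ratio))))))
  trends$significant <- trends$p < cfg$thresholds$trend_alpha

  # --- selection ----------------------------------------------------------
  say("predictor selection")
  cand <- unlist(cfg$hypotheses, use.names = FALSE)
  cand <- intersect(cand, names(predictors))
  hyp <- lapply(cfg$hypotheses, intersect, cand)
  hyp <- hyp[lengths(hyp) > 0]
  corr <- stats::cor(predictors[, cand, drop = FALSE],
                     use = "pairwise.complete.obs")
  screen <- list(); selection <- list()
  responses <- c(ratios, list(
    abundance = data.frame(year = counts$year[-nrow(counts)],
                           ratio = diff(log(counts$count)))))
  for (g in names(responses)) {
    resp <- data.frame(year = responses[[g]]$year,
                       value = responses[[g]][[2]])
    hyp_g <- hyp
    if (g == "non_timber") hyp_g$timber_harvest <- NULL
    if (g == "abundance") {
      hyp_g$timber_harvest <- NULL
      hyp_g$predation <- NULL
    }
    scr <- univariate_r2_screen(resp, predictors[, c("year",
                                                     unlist(hyp_g)),
                                                 drop = FALSE])
    screen[[g]] <- scr
    selection[[g]] <- select_representatives(
      scr, hyp_g, corr, threshold = cfg$thresholds$correlation)
  }

  # --- recruitment models --------------------------------------------------
  say("recruitment models")
  mcmc <- cfg$mcmc
  fits <- list()
  for (g in names(ratios)) {
    sel <- selection[[g]]$chosen
    dat <- merge(stats::setNames(ratios[[g]][, c("year", "ratio")],
                                 c("year", "ratio")),
                 predictors[, c("year", unname(sel)), drop = FALSE],
                 by = "year")
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    dat_std <- standardize_predictors(dat, cols = unname(sel))
    form <- stats::reformulate(unname(sel), response = "ratio")
    fits[[g]] <- fit_recruitment_glm(form, dat_std, config = mcmc,
                                     cri = cfg$thresholds$cri)
  }

  # --- abundance model -----------------------------------------------------
  say("Gompertz state-space model")
  sel_a <- selection$abundance$chosen
  cov_a <- predictors[, c("year", unname(sel_a)), drop = FALSE]
  cov_a <- cov_a[cov_a$year %in% counts$year, , drop = FALSE]
  # covariate gaps are rare interior years; carry the column mean
  for (v in unname(sel_a)) {
    miss <- !is.finite(cov_a[[v]])
    cov_a[[v]][miss] <- mean(cov_a[[v]], na.rm = TRUE)
  }
  cov_a <- standardize_predictors(cov_a, cols = unname(sel_a))
  ssm <- fit_gompertz_ssm(counts, harvest, cov_a, config = mcmc,
                          cri = cfg$thresholds$cri)

  say("density-dependence test")
  dd <- dennis_taper_test(counts, n_boot = cfg$n_boot, seed = seed + 16L)

  # --- outputs -------------------------------------------------------------
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("elkdyn")),
                   r_version = R.version.string,
                   n_years_counts = nrow(counts),
                   n_boot = cfg$n_boot,
                   mcmc = mcmc[c("chains", "iterations", "burn_in", "thin")])
  res <- list(config = cfg, predictors = predictors, bear = recon,
              ratios = ratios, counts = counts, trends = trends,
              screen = screen, selection = selection,
              recruitment = fits, abundance = ssm, ddtest = dd,
              exclusions = list(timber = flt_t$excluded,
                                non_timber = flt_n$excluded,
                                island_wide = flt_i$excluded),
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(predictors, file.path(out_dir, "predictors.csv"))
    write_table(summary(recon), file.path(out_dir, "bear_reconstruction.csv"))
    write_table(trends, file.path(out_dir, "trends.csv"))
    for (g in names(screen))
      write_table(screen[[g]], file.path(out_dir,
                                         paste0("screen_", g, ".csv")))
    for (g in names(fits))
      write_table(fits[[g]]$summary,
                  file.path(out_dir, paste0("model_", g, ".csv")))
    write_table(ssm$summary, file.path(out_dir, "model_abundance.csv"))
    write_table(data.frame(statistic = dd$statistic, p = dd$p.value,
                           n_boot = dd$n_boot),
                file.path(out_dir, "density_dependence.csv"))
    write_table(dd$growth, file.path(out_dir, "growth_diagnostic.csv"))
    for (g in names(res$exclusions))
      write_table(res$exclusions[[g]],
                  file.path(out_dir, paste0("exclusions_", g, ".csv")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  say("done")
  invisible(res)
}
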