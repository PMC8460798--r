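#' Configure an end-to-end emergence analysis run
#'
#' Exactly one input source: either paths to weather and emergence CSVs,
#' or a [sim_config()] that generates both. The run then accumulates
#' thermal time, builds per-site emergence curves, fits the early-season
#' Gompertz and full-season saturating-exponential models, inverts the
#' full-season fit to 50% and 75% benchmarks, detects the peak window,
#' summarises edaphic conditions, and (if predictors are supplied or
#' simulated) screens them.
#'
#' @param weather_csv,emergence_csv input file paths (both or neither).
#' @param simulation a [sim_config()] (alternative to the files).
#' @param season_year season to analyse; defaults to the simulation's year
#'   or the first year in the weather file.
#' @param base_temp base temperature, degrees C (default 21).
#' @param anchor anchor date; default June 21 of the season year.
#' @param direction `"below_base"` or `"above_base"`.
#' @param models which model kinds to fit.
#' @param early_ceiling early-season ceiling fraction (default 0.5).
#' @param window_weeks peak-window length (default 4).
#' @param screen_predictors simulate and screen a predictor panel
#'   (simulation runs only; default TRUE for simulations).
#' @param seed seed recorded in the report and used for any run-level
#'   randomness; defaults to the simulation's seed.
#' @return a `"run_config"` list (validated).
#' @export
run_config <- function(weather_csv = NULL, emergence_csv = NULL,
                       simulation = NULL, season_year = NULL,
                       base_temp = 21, anchor = NULL,
                       direction = c("below_base", "above_base"),
                       models = c("gompertz", "saturating_exp"),
                       early_ceiling = 0.5, window_weeks = 4,
                       screen_predictors = !is.null(simulation),
                       seed = NULL) {
  direction <- match.arg(direction)
  files <- !is.null(weather_csv) || !is.null(emergence_csv)
  if (files && is.null(weather_csv) != is.null(emergence_csv))
    stop("supply both weather_csv and emergence_csv, or neither")
  if (files && !is.null(simulation))
    stop("exactly one input source: files or simulation, not both")
  if (!files && is.null(simulation))
    stop("no input source: supply CSV paths or a sim_config")
  if (!is.null(simulation) && !inherits(simulation, "sim_config"))
    stop("`simulation` must be a sim_config object")
  stopifnot(is.finite(base_temp))
  if (is.null(seed))
    seed <- if (!is.null(simulation)) simulation$seed else 1L
  structure(list(weather_csv = weather_csv, emergence_csv = emergence_csv,
                 simulation = simulation, season_year = season_year,
                 base_temp = base_temp, anchor = anchor,
                 direction = direction, models = models,
                 early_ceiling = early_ceiling,
                 window_weeks = window_weeks,
                 screen_predictors = isTRUE(screen_predictors),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full emergence analysis pipeline
#'
#' Executes every stage of [run_config()]'s plan and returns a
#' machine-readable report. Stage errors are re-raised with the stage name
#' attached. Re-running on identical inputs (same config, same seed) is
#' idempotent and yields an identical report.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, `report.json` and
#'   per-site curve CSVs are written there.
#' @return an `"emergence_report"` list: header (seed, inputs), per-site
#'   fits with metrics and benchmarks, peak window, edaphic summary,
#'   weekly-share table, and screen results when requested.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }

  sim <- config$simulation
  weather <- stage("ingest", {
    if (!is.null(sim)) simulate_weather(sim)
    else read_weather_csv(config$weather_csv)
  })
  records <- stage("ingest", {
    if (!is.null(sim)) simulate_emergence(weather, sim)
    else read_emergence_csv(config$emergence_csv)
  })
  season_year <- config$season_year %||%
    (if (!is.null(sim)) sim$season_year
     else as.integer(format(min(records$date), "%Y")))
  anchor <- as.Date(config$anchor %||% sprintf("%d-06-21", season_year))

  tts <- stage("thermal_time",
    thermal_time(weather, base_temp = config$base_temp,
                 anchor_date = anchor, direction = config$direction))

  sites <- unique(records$site_id)
  site_results <- lapply(sites, function(site) {
    curve <- stage("curves",
      suppressWarnings(build_emergence_curve(records, tts, season_year,
                                             site = site)))
    fits <- list()
    if ("gompertz" %in% config$models)
      fits$gompertz <- stage("fit",
        fit_emergence(early_season(curve, config$early_ceiling), "gompertz"))
    if ("saturating_exp" %in% config$models)
      fits$saturating_exp <- stage("fit",
        fit_emergence(curve, "saturating_exp"))

    benchmarks <- NULL
    if (!is.null(fits$saturating_exp)) {
      benchmarks <- stage("benchmarks", {
        rng <- model_range("saturating_exp",
                           as.list(coef(fits$saturating_exp)))
        bm <- lapply(c(cdd_at_50 = 0.5, cdd_at_75 = 0.75), function(tg) {
          if (tg <= rng[1] || tg >= rng[2]) return(NULL)
          cdd <- cdd_at_fraction(fits$saturating_exp, tg)
          date <- tryCatch(date_at_thermal_time(tts, cdd, site = site),
                           error = function(e) NA)
          list(cdd = cdd, date = if (is.na(date)) NA else format(date))
        })
        bm[!vapply(bm, is.null, logical(1))]
      })
    }
    w_site <- weather_series(as.data.frame(weather)[weather$site_id == site, ])
    pw <- stage("windows",
      peak_window(curve, w_site, weeks = config$window_weeks))
    shares <- stage("windows", weekly_shares(curve))
    list(site_id = site, curve = curve, fits = fits,
         benchmarks = benchmarks, peak_window = pw, weekly_shares = shares,
         weather = w_site)
  })
  names(site_results) <- sites

  rapid <- stage("windows",
    rapid_change_weeks(lapply(site_results, `[[`, "weekly_shares"),
                       span_weeks = config$window_weeks))
  edaphic <- stage("windows", {
    ranges <- lapply(site_results, function(s)
      c(s$peak_window$start_date, s$peak_window$end_date))
    edaphic_summary(lapply(site_results, `[[`, "weather"), unname(ranges))
  })

  screen <- NULL
  if (config$screen_predictors && !is.null(sim)) {
    screen <- stage("screen", {
      sp <- simulate_predictors(sim)
      pearson_screen(sp$predictors, sp$response)
    })
  }

  report <- build_report(config, season_year, anchor, tts, site_results,
                         rapid, edaphic, screen)
  validate_report(report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    for (s in site_results)
      utils::write.csv(as.data.frame(s$curve),
                       file.path(out_dir, paste0("curve_", s$site_id, ".csv")),
                       row.names = FALSE)
  }
  report
}

build_report <- function(config, season_year, anchor, tts, site_results,
                         rapid, edaphic, screen) {
  fit_block <- function(f) {
    if (is.null(f)) return(NULL)
    list(kind = f$kind,
         params = as.list(coef(f)),
         metrics = f$metrics,
         n_points = f$n,
         converged = f$converged)
  }
  sites <- lapply(site_results, function(s) {
    list(site_id = s$site_id,
         season_year = season_year,
         yearly_total = attr(s$curve, "yearly_total"),
         n_observations = nrow(s$curve),
         final_cdd = max(s$curve$cdd),
         fits = lapply(s$fits, fit_block),
         benchmarks = s$benchmarks,
         peak_window = list(
           start = format(s$peak_window$start_date),
           end = format(s$peak_window$end_date),
           length_weeks = s$peak_window$length_weeks,
           share = s$peak_window$share,
           cdd_span = s$peak_window$cdd_span,
           summaries = s$peak_window$summaries),
         weekly_shares = s$weekly_shares)
  })
  structure(list(
    header = list(seed = config$seed,
                  season_year = season_year,
                  anchor_date = format(anchor),
                  base_temp = config$base_temp,
                  direction = config$direction,
                  source = if (is.null(config$simulation)) "files"
                           else "simulation"),
    sites = sites,
    rapid_change = list(week_range = rapid$week_range,
                        per_week = rapid$summary),
    edaphic = list(window_days = edaphic$window_days,
                   n_site_years = edaphic$n_site_years,
                   mean = as.list(edaphic$mean),
                   spread = as.list(edaphic$spread)),
    screen = if (!is.null(screen)) as.data.frame(screen) else NULL),
    class = "emergence_report")
}

#' Structural validation of a pipeline report
#'
#' Checks a report against the shipped schema
#' (`inst/extdata/report-schema.json`): required top-level and per-site
#' fields, types of the header, and fraction-valued shares. Errors on the
#' first violation.
#'
#' @param report an `"emergence_report"`.
#' @return `TRUE`, invisibly.
#' @export
validate_report <- function(report) {
  need <- c("header", "sites", "rapid_change", "edaphic")
  miss <- setdiff(need, names(report))
  if (length(miss))
    stop("report lacks section(s): ", paste(miss, collapse = ", "))
  h <- report$header
  for (f in c("seed", "season_year", "anchor_date", "base_temp",
              "direction", "source"))
    if (is.null(h[[f]])) stop("report header lacks field: ", f)
  if (!length(report$sites)) stop("report has no site blocks")
  for (s in report$sites) {
    for (f in c("site_id", "yearly_total", "fits", "peak_window"))
      if (is.null(s[[f]])) stop("site block lacks field: ", f)
    sh <- s$peak_window$share
    if (!is.numeric(sh) || sh < 0 || sh > 1)
      stop("peak-window share outside [0, 1]")
  }
  invisible(TRUE)
}

#' @export
print.emergence_report <- function(x, ...) {
  h <- x$header
  cat(sprintf("Emergence analysis report (season %d, anchor %s, base %g C)\n",
              h$season_year, h$anchor_date, h$base_temp))
  for (s in x$sites) {
    cat(sprintf("  %s: total %d seedlings over %d visits\n",
                s$site_id, s$yearly_total, s$n_observations))
    for (f in s$fits)
      cat(sprintf("    %s: a=%.4g b=%.4g c=%.4g (R2 %.3f)\n", f$kind,
                  f$params$a, f$params$b, f$params$c, f$metrics$r2))
    for (nm in names(s$benchmarks))
      cat(sprintf("    %s: %.1f degree days (%s)\n", nm,
                  s$benchmarks[[nm]]$cdd, s$benchmarks[[nm]]$date))
    cat(sprintf("    peak window %s to %s: %.0f%% of yearly total\n",
                s$peak_window$start, s$peak_window$end,
                100 * s$peak_window$share))
  }
  cat(sprintf("  rapid change: weeks %d-%d\n",
              x$rapid_change$week_range[1], x$rapid_change$week_range[2]))
  invisible(x)
}
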