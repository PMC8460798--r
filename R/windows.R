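#' Detect the peak-emergence window
#'
#' Slides a window of `weeks` weeks over the observation dates of an
#' emergence curve and returns the contiguous window capturing the largest
#' share of yearly emergence (ties broken by earliest start). Candidate
#' windows start at each observation date and span `weeks * 7` calendar
#' days; a count belongs to a window when its observation date falls inside.
#' Weather summaries (mean air temperature, mean soil temperature, total
#' rainfall) are computed over the window's calendar days when a weather
#' series is supplied.
#'
#' @param curve an `"emergence_curve"`.
#' @param weather optional [weather_series()] for the same site.
#' @param weeks window length in weeks (default 4).
#' @return a `"peak_window"` list: `start_date`, `end_date`, `length_weeks`,
#'   `share`, `cdd_span`, and `summaries` (means/total over window days; `NA`
#'   where the weather field is absent).
#' @examples
#' # uniform weekly emergence over 10 weeks, 4-week window -> share 0.4
#' @export
peak_window <- function(curve, weather = NULL, weeks = 4) {
  stopifnot(inherits(curve, "emergence_curve"), weeks >= 1)
  span <- as.integer(max(curve$date) - min(curve$date)) + 1L
  if (span < weeks * 7L)
    stop("curve spans ", span, " days; shorter than a ", weeks, "-week window")
  total <- attr(curve, "yearly_total")
  best_start <- NULL; best_count <- -1
  for (i in seq_len(nrow(curve))) {
    s <- curve$date[i]
    e <- s + weeks * 7L - 1L
    cnt <- sum(curve$count[curve$date >= s & curve$date <= e])
    if (cnt > best_count) { best_count <- cnt; best_start <- s }
  }
  start <- best_start
  end <- start + weeks * 7L - 1L
  inwin <- curve$date >= start & curve$date <= end
  summaries <- list(mean_air_temp = NA_real_, mean_soil_temp = NA_real_,
                    total_rainfall = NA_real_)
  if (!is.null(weather)) {
    w <- as.data.frame(weather)
    w <- w[w$date >= start & w$date <= end, , drop = FALSE]
    if (!is.null(w$t_air_mean)) summaries$mean_air_temp <- mean(w$t_air_mean)
    if (!is.null(w$t_soil_5cm)) summaries$mean_soil_temp <- mean(w$t_soil_5cm)
    if (!is.null(w$rainfall)) summaries$total_rainfall <- sum(w$rainfall)
  }
  structure(list(start_date = start, end_date = end,
                 length_weeks = as.integer(weeks),
                 share = best_count / total,
                 cdd_span = range(curve$cdd[inwin]),
                 summaries = summaries),
            class = "peak_window")
}

#' @export
print.peak_window <- function(x, ...) {
  cat(sprintf("Peak %d-week emergence window: %s to %s (%.0f%% of yearly total)\n",
              x$length_weeks, format(x$start_date), format(x$end_date),
              100 * x$share))
  cat(sprintf("  thermal-time span: %.0f to %.0f degree days\n",
              x$cdd_span[1], x$cdd_span[2]))
  s <- x$summaries
  if (is.finite(s$mean_soil_temp) || is.finite(s$total_rainfall))
    cat(sprintf("  mean air %.1f C, mean soil %.1f C, rainfall %.1f mm\n",
                s$mean_air_temp, s$mean_soil_temp, s$total_rainfall))
  invisible(x)
}

#' Weeks of most rapid emergence change across site-years
#'
#' Pools weekly emergence shares from several site-years, summarises each
#' week of the year by percentiles across site-years (min, 25, 50, 75, max
#' — the box-plot view), and reports the contiguous span of weeks whose
#' summed median share is largest, i.e. where emergence typically changes
#' fastest.
#'
#' @param shares_list list of weekly-share data frames from
#'   [weekly_shares()], one per site-year.
#' @param span_weeks length of the reported range, in weeks (default 4).
#' @return a list with `week_range` (first and last week of year of the
#'   detected span) and `summary`, a data frame of per-week percentiles.
#' @export
rapid_change_weeks <- function(shares_list, span_weeks = 4) {
  if (inherits(shares_list, "data.frame")) shares_list <- list(shares_list)
  stopifnot(length(shares_list) >= 1, span_weeks >= 1)
  weeks <- sort(unique(unlist(lapply(shares_list, `[[`, "week"))))
  mat <- vapply(shares_list, function(s) {
    v <- setNames(rep(0, length(weeks)), weeks)
    v[as.character(s$week)] <- s$share
    v
  }, numeric(length(weeks)))
  mat <- matrix(mat, nrow = length(weeks))
  q <- t(apply(mat, 1, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1)))
  summary <- data.frame(week = weeks, min = q[, 1], p25 = q[, 2],
                        median = q[, 3], p75 = q[, 4], max = q[, 5],
                        row.names = NULL)
  # best contiguous run of consecutive week numbers maximizing summed median
  best <- NULL; best_sum <- -Inf
  for (w0 in weeks) {
    run <- w0:(w0 + span_weeks - 1L)
    if (!all(run %in% weeks) && w0 + span_weeks - 1L > max(weeks)) next
    s <- sum(summary$median[summary$week %in% run])
    if (s > best_sum) { best_sum <- s; best <- c(w0, w0 + span_weeks - 1L) }
  }
  list(week_range = best, summary = summary)
}

#' Trailing rolling means of soil temperature and rainfall
#'
#' Seven-day (by default) trailing means of 5-cm soil temperature and
#' rainfall, ending at each date — the edaphic summary used to
#' characterise conditions during rapid emergence. The first
#' `window_days - 1` dates have no complete window and carry `NA`.
#'
#' @param weather a [weather_series()] for one site.
#' @param window_days trailing window length in days (default 7).
#' @param fields columns to roll (default soil temperature and rainfall;
#'   only those present are used).
#' @return data frame of `date` plus one `<field>_roll` column per field.
#' @export
rolling_edaphic <- function(weather, window_days = 7,
                            fields = c("t_soil_5cm", "rainfall")) {
  stopifnot(window_days >= 1)
  w <- as.data.frame(weather)
  if (length(unique(w$site_id)) > 1) stop("one site at a time")
  fields <- intersect(fields, names(w))
  if (!length(fields)) stop("weather series lacks the requested field(s)")
  out <- data.frame(date = w$date)
  for (f in fields) {
    roll <- stats::filter(w[[f]], rep(1 / window_days, window_days),
                          sides = 1)
    out[[paste0(f, "_roll")]] <- as.numeric(roll)
  }
  out
}

#' Summarise rolling edaphic conditions over a window, across site-years
#'
#' For each site-year (a weather series plus a date range), averages the
#' trailing rolling means inside the range; then reports the mean and the
#' across-site-year spread (standard deviation) of those averages — e.g.
#' "seven-day mean soil temperature during the rapid-emergence weeks,
#' consistent across years".
#'
#' @param weather_list list of [weather_series()] (one per site-year), or a
#'   single series.
#' @param ranges list of `c(start, end)` date pairs, one per series (or one
#'   pair recycled).
#' @param window_days trailing window length (default 7).
#' @return an `"edaphic_summary"` list with per-field `mean` and `spread`
#'   (sd across site-years; `NA` with a single site-year).
#' @export
edaphic_summary <- function(weather_list, ranges, window_days = 7) {
  if (inherits(weather_list, "weather_series"))
    weather_list <- list(weather_list)
  if (!is.list(ranges)) ranges <- list(ranges)  # one c(start, end) pair
  if (length(ranges) == 1) ranges <- rep(ranges, length(weather_list))
  stopifnot(length(ranges) == length(weather_list))
  per_year <- lapply(seq_along(weather_list), function(i) {
    roll <- rolling_edaphic(weather_list[[i]], window_days)
    rng <- as.Date(ranges[[i]])
    sel <- roll$date >= rng[1] & roll$date <= rng[2]
    vals <- roll[sel, setdiff(names(roll), "date"), drop = FALSE]
    if (!nrow(vals) || all(!stats::complete.cases(vals)))
      stop("no complete ", window_days, "-day window inside range ",
           format(rng[1]), " to ", format(rng[2]))
    colMeans(vals, na.rm = TRUE)
  })
  m <- do.call(rbind, per_year)
  structure(list(
    n_site_years = nrow(m),
    window_days = window_days,
    mean = colMeans(m),
    spread = apply(m, 2, function(x) if (length(x) > 1) stats::sd(x)
                   else NA_real_)),
    class = "edaphic_summary")
}

#' @export
print.edaphic_summary <- function(x, ...) {
  cat(sprintf("Edaphic summary (%d-day trailing means, %d site-year(s)):\n",
              x$window_days, x$n_site_years))
  for (f in names(x$mean))
    cat(sprintf("  %s: %.2f (spread %.3f)\n", f, x$mean[f], x$spread[f]))
  invisible(x)
}

#' Mean day and night air temperatures from sub-daily readings
#'
#' Splits sub-daily air-temperature readings at fixed clock hours — day is
#' 07:00 to 19:00 local (a civil-daylight proxy), night is the complement —
#' and averages each side over a date window.
#'
#' @param timestamps POSIXct reading times.
#' @param values air temperatures, degrees C.
#' @param window optional `c(start, end)` dates restricting the readings.
#' @param day_hours `c(start_hour, end_hour)` for the day block
#'   (default `c(7, 19)`, half-open: `hour >= 7 & hour < 19`).
#' @return named vector `c(day = , night = )`.
#' @export
day_night_means <- function(timestamps, values, window = NULL,
                            day_hours = c(7, 19)) {
  stopifnot(length(timestamps) == length(values))
  if (!inherits(timestamps, "POSIXct"))
    stop("sub-daily data required: timestamps must be POSIXct")
  if (!is.null(window)) {
    d <- as.Date(timestamps)
    keep <- d >= as.Date(window[1]) & d <= as.Date(window[2])
    timestamps <- timestamps[keep]; values <- values[keep]
  }
  if (!length(values)) stop("no readings in window")
  hr <- as.integer(format(timestamps, "%H")) +
    as.integer(format(timestamps, "%M")) / 60
  is_day <- hr >= day_hours[1] & hr < day_hours[2]
  c(day = mean(values[is_day]), night = mean(values[!is_day]))
}
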