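#' Reduce sub-daily temperature readings to daily means
#'
#' Field loggers in this design record on 15-minute intervals; the degree-day
#' machinery works on one value per day. Two reduction conventions are
#' offered: the arithmetic mean of all readings in the day, or the midpoint
#' of the daily minimum and maximum (the convention of stations that log
#' only extremes).
#'
#' Calendar days between the first and last reading that contain no readings
#' are omitted with a warning; non-finite readings are rejected.
#'
#' @param timestamps POSIXct vector of reading times.
#' @param values numeric temperatures (degrees C), same length.
#' @param convention `"mean_of_readings"` (default) or `"minmax_midpoint"`.
#' @return data frame with columns `date` and `t_mean`, one row per day
#'   that has readings.
#' @examples
#' ts <- as.POSIXct("2019-07-01 08:00", tz = "UTC") + c(0, 12 * 3600)
#' daily_mean_temperature(ts, c(10, 20))  # 15
#' @export
daily_mean_temperature <- function(timestamps, values,
                                   convention = c("mean_of_readings",
                                                  "minmax_midpoint")) {
  convention <- match.arg(convention)
  stopifnot(length(timestamps) == length(values), length(values) >= 1)
  if (any(!is.finite(values)))
    stop("non-finite temperature reading(s)")
  day <- as.Date(timestamps, tz = attr(timestamps, "tzone") %||% "UTC")
  agg <- if (convention == "mean_of_readings") {
    tapply(values, day, mean)
  } else {
    tapply(values, day, function(v) (min(v) + max(v)) / 2)
  }
  dates <- as.Date(names(agg))
  full <- seq(min(dates), max(dates), by = "day")
  empty <- setdiff(format(full), format(dates))
  if (length(empty))
    warning("day(s) with no readings omitted: ", paste(empty, collapse = ", "))
  data.frame(date = dates, t_mean = as.numeric(agg), row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accumulate degree days from an anchor date
#'
#' Converts a daily weather series into a thermal-time series: per-day
#' degree-day increments relative to a base temperature, and their running
#' accumulation from an anchor date. The study's driver is cooling degree
#' days with a 21 degree C base accumulated from the summer solstice
#' (CDD21C): `direction = "below_base"` credits `max(0, base - T)` per day.
#' `"above_base"` gives the growing-degree-day counterpart
#' `max(0, T - base)`.
#'
#' The day containing the anchor is the first accumulation day (closed
#' start); days before the anchor are excluded. A missing calendar day
#' between the anchor and the end of the series is a hard error — silent
#' interpolation would let degree-day totals drift.
#'
#' @param weather a [weather_series()].
#' @param base_temp base temperature, degrees C (default 21).
#' @param anchor_date accumulation start (Date or ISO string); default is
#'   June 21 of the first year in the series (northern-hemisphere summer
#'   solstice).
#' @param direction `"below_base"` (cooling degree days, default) or
#'   `"above_base"` (growing degree days).
#' @param temp_field which temperature column drives accumulation
#'   (default `"t_air_mean"`).
#' @return a `"thermal_time"` data frame with columns `site_id`, `date`,
#'   `temp`, `increment`, `cumulative` and attributes `base_temp`,
#'   `anchor_date`, `direction`, `temp_field`.
#' @examples
#' w <- weather_series(data.frame(site_id = "a",
#'                                date = as.Date("2019-06-21") + 0:4,
#'                                t_air_mean = c(22, 20, 19, 23, 15)))
#' tt <- thermal_time(w, base_temp = 21)
#' tt$cumulative  # 0 1 3 3 9
#' @export
thermal_time <- function(weather, base_temp = 21, anchor_date = NULL,
                         direction = c("below_base", "above_base"),
                         temp_field = "t_air_mean") {
  direction <- match.arg(direction)
  if (!inherits(weather, "weather_series")) weather <- weather_series(weather)
  stopifnot(is.finite(base_temp))
  if (!temp_field %in% names(weather))
    stop("temperature field '", temp_field, "' not present in weather series")
  if (is.null(anchor_date))
    anchor_date <- as.Date(sprintf("%d-06-21",
                                   as.integer(format(min(weather$date), "%Y"))))
  anchor_date <- as.Date(anchor_date)

  out <- lapply(split(as.data.frame(weather), weather$site_id), function(w) {
    if (anchor_date < min(w$date) || anchor_date > max(w$date))
      stop("anchor date ", format(anchor_date),
           " outside weather range for site '", w$site_id[1], "' (",
           format(min(w$date)), " to ", format(max(w$date)), ")")
    w <- w[w$date >= anchor_date, , drop = FALSE]
    full <- seq(anchor_date, max(w$date), by = "day")
    gap <- setdiff(format(full), format(w$date))
    if (length(gap))
      stop("missing weather day(s) for site '", w$site_id[1], "': ",
           paste(utils::head(gap, 5), collapse = ", "),
           if (length(gap) > 5) sprintf(" (and %d more)", length(gap) - 5))
    temp <- w[[temp_field]]
    if (anyNA(temp))
      stop("missing ", temp_field, " value(s) for site '", w$site_id[1],
           "' after the anchor date")
    inc <- if (direction == "below_base") pmax(0, base_temp - temp)
           else pmax(0, temp - base_temp)
    data.frame(site_id = w$site_id, date = w$date, temp = temp,
               increment = inc, cumulative = cumsum(inc), row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res,
            base_temp = base_temp, anchor_date = anchor_date,
            direction = direction, temp_field = temp_field,
            class = c("thermal_time", "data.frame"))
}

#' @export
print.thermal_time <- function(x, ...) {
  cat(sprintf("Thermal time: %s base %g C, anchored %s\n",
              if (attr(x, "direction") == "below_base") "cooling degree days"
              else "growing degree days",
              attr(x, "base_temp"), format(attr(x, "anchor_date"))))
  for (site in unique(x$site_id)) {
    s <- x[x$site_id == site, ]
    cat(sprintf("  %s: %d days, final accumulation %.1f degree-days\n",
                site, nrow(s), max(s$cumulative)))
  }
  invisible(x)
}

site_slice <- function(tts, site) {
  sites <- unique(tts$site_id)
  if (is.null(site)) {
    if (length(sites) > 1)
      stop("multiple sites present; specify `site`")
    site <- sites
  }
  s <- tts[tts$site_id == site, , drop = FALSE]
  if (!nrow(s)) stop("no such site: '", site, "'")
  s
}

#' First date at which a thermal-time accumulation is reached
#'
#' Returns the first date whose cumulative degree-day total is at least
#' `target` (first-crossing). The companion [thermal_time_at_date()] is the
#' exact per-day inverse lookup.
#'
#' @param tts a `"thermal_time"` series from [thermal_time()].
#' @param target degree days, `>= 0`.
#' @param site site to query when the series holds several.
#' @return a `Date`.
#' @export
date_at_thermal_time <- function(tts, target, site = NULL) {
  stopifnot(is.numeric(target), length(target) == 1, target >= 0)
  s <- site_slice(tts, site)
  i <- which(s$cumulative >= target)
  if (!length(i))
    stop(sprintf("target %.3f degree-days not reached in series (final %.3f)",
                 target, max(s$cumulative)))
  s$date[min(i)]
}

#' Cumulative thermal time on a given date
#'
#' @param tts a `"thermal_time"` series.
#' @param date calendar day (Date or ISO string); must be a day in the series.
#' @param site site to query when the series holds several.
#' @return cumulative degree days at `date`.
#' @export
thermal_time_at_date <- function(tts, date, site = NULL) {
  date <- as.Date(date)
  s <- site_slice(tts, site)
  i <- match(format(date), format(s$date))
  if (anyNA(i))
    stop("date(s) not in thermal-time series: ",
         paste(format(date[is.na(i)]), collapse = ", "))
  s$cumulative[i]
}
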