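#' Construct and validate a daily weather series
#'
#' A weather series is a data frame with one row per site-day holding the
#' environmental record the emergence models consume: mean (and optionally
#' min/max) air temperature, soil temperature at 5 cm, rainfall, and
#' optionally volumetric soil moisture and daily light integral.
#'
#' Validation enforces: strictly increasing, duplicate-free dates within each
#' site; non-negative rainfall; soil moisture within \[0, 1\] where present;
#' and `t_air_min <= t_air_mean <= t_air_max` wherever all three are present.
#'
#' @param data data frame with columns `site_id`, `date` (Date or ISO-8601
#'   string) and at least one of the temperature fields; optional columns:
#'   `t_air_mean`, `t_air_min`, `t_air_max`, `t_soil_5cm`, `rainfall`,
#'   `soil_moisture`, `dli`.
#' @return the validated data frame, dates as `Date`, classed
#'   `"weather_series"`.
#' @examples
#' w <- weather_series(data.frame(site_id = "a",
#'                                date = as.Date("2019-06-21") + 0:4,
#'                                t_air_mean = c(25, 24, 26, 23, 22),
#'                                rainfall = c(0, 4, 0, 0, 12)))
#' @export
weather_series <- function(data) {
  stopifnot(is.data.frame(data))
  required <- c("site_id", "date")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("weather series lacks column(s): ", paste(missing_cols, collapse = ", "))
  data$site_id <- as.character(data$site_id)
  data$date <- as.Date(data$date)
  if (anyNA(data$date)) stop("unparseable dates in weather series")

  for (site in unique(data$site_id)) {
    d <- data$date[data$site_id == site]
    if (anyDuplicated(d))
      stop("duplicate dates for site '", site, "'")
    if (is.unsorted(d, strictly = TRUE))
      stop("dates not strictly increasing for site '", site, "'")
  }
  if (!is.null(data$rainfall) && any(data$rainfall < 0, na.rm = TRUE))
    stop("negative rainfall")
  if (!is.null(data$soil_moisture) &&
      any(data$soil_moisture < 0 | data$soil_moisture > 1, na.rm = TRUE))
    stop("soil_moisture outside [0, 1]")
  if (all(c("t_air_min", "t_air_mean", "t_air_max") %in% names(data))) {
    ok <- is.na(data$t_air_min) | is.na(data$t_air_mean) | is.na(data$t_air_max) |
      (data$t_air_min <= data$t_air_mean & data$t_air_mean <= data$t_air_max)
    if (!all(ok))
      stop("t_air_min <= t_air_mean <= t_air_max violated on ",
           sum(!ok), " day(s)")
  }
  class(data) <- c("weather_series", "data.frame")
  data
}

#' Read a weather CSV
#'
#' One row per site-day; header
#' `site_id,date,t_air_mean,t_air_min,t_air_max,t_soil_5cm,rainfall,soil_moisture,dli`
#' (optional columns may be absent or left empty); dates ISO-8601.
#'
#' @param path path to the CSV file.
#' @return a [weather_series()].
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  weather_series(df)
}

#' Write a weather series to CSV
#'
#' @param weather a [weather_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(weather, path) {
  utils::write.csv(as.data.frame(weather), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.weather_series <- function(x, ...) {
  sites <- unique(x$site_id)
  cat("Weather series:", length(sites), "site(s),", nrow(x), "site-days\n")
  cat("  dates:", format(min(x$date)), "to", format(max(x$date)), "\n")
  cat("  fields:", paste(setdiff(names(x), c("site_id", "date")), collapse = ", "), "\n")
  invisible(x)
}
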