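#' Validate dated seedling-count records
#'
#' Raw field observations: newly emerged seedlings counted (and removed)
#' inside a monitoring area on each visit. Counts must be non-negative
#' integers and each (site, plot, date) combination unique.
#'
#' @param data data frame with columns `site_id`, `plot_id`, `date`,
#'   `new_seedlings`.
#' @return the validated data frame, classed `"emergence_records"`.
#' @export
emergence_records <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("site_id", "plot_id", "date", "new_seedlings")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("emergence records lack column(s): ", paste(miss, collapse = ", "))
  data$site_id <- as.character(data$site_id)
  data$plot_id <- as.character(data$plot_id)
  data$date <- as.Date(data$date)
  if (anyNA(data$date)) stop("unparseable dates in emergence records")
  n <- data$new_seedlings
  if (anyNA(n) || any(n < 0) || any(n != round(n)))
    stop("new_seedlings must be non-negative integers")
  data$new_seedlings <- as.integer(round(n))
  key <- paste(data$site_id, data$plot_id, format(data$date))
  if (anyDuplicated(key))
    stop("duplicate (site, plot, date) record(s)")
  class(data) <- c("emergence_records", "data.frame")
  data
}

#' Read an emergence-count CSV
#'
#' Header `site_id,plot_id,date,new_seedlings`; ISO dates.
#'
#' @param path path to the CSV file.
#' @return an [emergence_records()] data frame.
#' @export
read_emergence_csv <- function(path) {
  emergence_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Build a cumulative emergence curve aligned to thermal time
#'
#' Accumulates dated seedling counts for one site and season into a
#' yearly-cumulative emergence curve: per observation date, the cumulative
#' count, the cumulative fraction of the yearly total, and the thermal-time
#' accumulation (degree days) at that date. A season is a calendar year
#' (autumn-contained emergence; no cross-year seasons).
#'
#' Plots are pooled by summing counts per date by default, matching the
#' one-curve-per-site-year reporting of replicated monitoring designs;
#' `pooling = "per_plot"` instead returns one curve per plot for dispersion
#' work. Observation dates before the thermal-time anchor are excluded with
#' a warning (no thermal time is defined for them).
#'
#' @param records an [emergence_records()] data frame (or coercible).
#' @param tts a `"thermal_time"` series from [thermal_time()] covering all
#'   retained observation dates.
#' @param season_year calendar year of the season.
#' @param pooling `"sum_plots"` (default) or `"per_plot"`.
#' @param site site to build when records hold several.
#' @return an `"emergence_curve"` data frame with columns `date`, `cdd`,
#'   `count`, `cum_count`, `cum_fraction` and attributes `site_id`,
#'   `season_year`, `yearly_total`; for `pooling = "per_plot"`, a named list
#'   of such curves.
#' @examples
#' # counts 5, 5, 10 -> cumulative fractions 0.25, 0.50, 1.00
#' @export
build_emergence_curve <- function(records, tts, season_year,
                                  pooling = c("sum_plots", "per_plot"),
                                  site = NULL) {
  pooling <- match.arg(pooling)
  if (!inherits(records, "emergence_records"))
    records <- emergence_records(records)
  r <- records[as.integer(format(records$date, "%Y")) == season_year, ,
               drop = FALSE]
  if (!is.null(site)) r <- r[r$site_id == site, , drop = FALSE]
  sites <- unique(r$site_id)
  if (length(sites) != 1)
    stop("records must cover exactly one site (found ", length(sites),
         "); use `site` to select")
  anchor <- attr(tts, "anchor_date")
  before <- r$date < anchor
  if (any(before)) {
    warning(sum(before), " observation(s) before the thermal-time anchor ",
            format(anchor), " excluded")
    r <- r[!before, , drop = FALSE]
  }
  if (pooling == "per_plot") {
    out <- lapply(split(r, r$plot_id), function(p)
      curve_from_counts(p, tts, sites, season_year))
    return(out)
  }
  curve_from_counts(r, tts, sites, season_year)
}

curve_from_counts <- function(r, tts, site, season_year) {
  counts <- tapply(r$new_seedlings, format(r$date), sum)
  dates <- as.Date(names(counts))
  o <- order(dates)
  dates <- dates[o]
  counts <- as.integer(counts[o])
  total <- sum(counts)
  if (total == 0)
    stop("no emergence observed for site '", site, "' in ", season_year)
  cum <- cumsum(counts)
  curve <- data.frame(
    date = dates,
    cdd = thermal_time_at_date(tts, dates, site = site),
    count = counts,
    cum_count = cum,
    cum_fraction = cum / total,
    row.names = NULL)
  structure(curve, site_id = site, season_year = season_year,
            yearly_total = total,
            anchor_date = attr(tts, "anchor_date"),
            class = c("emergence_curve", "data.frame"))
}

#' @export
print.emergence_curve <- function(x, ...) {
  cat(sprintf("Emergence curve: site %s, season %d\n",
              attr(x, "site_id"), attr(x, "season_year")))
  cat(sprintf("  %d observation dates, yearly total %d seedlings, final CDD %.1f\n",
              nrow(x), attr(x, "yearly_total"), max(x$cdd)))
  invisible(x)
}

#' Early-season portion of an emergence curve
#'
#' The early-season emergence model is fitted to the 0-to-50%-of-yearly-total
#' part of the curve. This keeps every point with cumulative fraction at or
#' below the ceiling, plus the first point exceeding it (so a fit sees the
#' crossing).
#'
#' @param curve an `"emergence_curve"`.
#' @param ceiling fraction in (0, 1]; default 0.5.
#' @return the trimmed `"emergence_curve"` (attributes preserved).
#' @export
early_season <- function(curve, ceiling = 0.5) {
  stopifnot(inherits(curve, "emergence_curve"),
            ceiling > 0, ceiling <= 1)
  keep <- curve$cum_fraction <= ceiling
  over <- which(!keep)
  if (length(over)) keep[min(over)] <- TRUE
  at <- attributes(curve)
  out <- curve[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out) <- c(attributes(out),
                       at[c("site_id", "season_year", "yearly_total",
                            "anchor_date")])
  class(out) <- at$class
  out
}

#' Weekly shares of yearly emergence
#'
#' Assigns each observation's count to a week of the year and returns each
#' week's share of the yearly total. An observation whose interval since the
#' previous visit exceeds one week (the June-August biweekly cadence) has
#' its count split evenly across the distinct weeks the interval covers,
#' so biweekly counts map onto a weekly axis without artificial spikes.
#'
#' @param curve an `"emergence_curve"`.
#' @param week_convention `"iso"` (ISO-8601 week of year, default) or
#'   `"doy"` (day-of-year division: `(doy - 1) %/% 7 + 1`).
#' @return data frame with columns `week` and `share`; shares sum to 1.
#' @export
weekly_shares <- function(curve, week_convention = c("iso", "doy")) {
  week_convention <- match.arg(week_convention)
  stopifnot(inherits(curve, "emergence_curve"), nrow(curve) >= 1)
  week_of <- function(d) {
    if (week_convention == "iso") as.integer(strftime(d, "%V"))
    else (as.integer(strftime(d, "%j")) - 1L) %/% 7L + 1L
  }
  total <- attr(curve, "yearly_total")
  acc <- numeric(0)  # named accumulator, week -> count
  add <- function(acc, wk, amount) {
    k <- as.character(wk)
    acc[k] <- (if (k %in% names(acc)) acc[k] else 0) + amount
    acc
  }
  prev <- NULL
  for (i in seq_len(nrow(curve))) {
    d <- curve$date[i]
    cnt <- curve$count[i]
    interval_days <- if (is.null(prev)) 1L else as.integer(d - prev)
    if (interval_days > 7L) {
      days <- seq(prev + 1L, d, by = "day")
      wks <- unique(week_of(days))
      for (w in wks) acc <- add(acc, w, cnt / length(wks))
    } else {
      acc <- add(acc, week_of(d), cnt)
    }
    prev <- d
  }
  wk <- as.integer(names(acc))
  o <- order(wk)
  data.frame(week = wk[o], share = as.numeric(acc)[o] / total)
}
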