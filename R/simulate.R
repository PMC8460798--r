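#' Simulation configuration with known ground truth
#'
#' Bundles every knob of the synthetic study: a temperate annual
#' temperature cycle with day-level noise, episodic rainfall, a true
#' emergence model driven by cooling-degree-day accumulation, a seedbank
#' size, and the field monitoring cadence (weekly January-May, biweekly
#' June-August, weekly September-December). Defaults emulate the
#' east-Tennessee study system: annual mean 15.5 C with amplitude 11 C
#' peaking in mid-July (day 200), 2 C day-to-day noise, 30% wet days
#' averaging 9 mm, a 10,000-seed seedbank per site, and a Gompertz truth
#' with asymptote 0.485 (fraction of the seedbank emerging over the
#' season).
#'
#' @param seed integer RNG seed; every downstream draw derives from it.
#' @param n_sites number of sites.
#' @param n_plots monitored plots per site (seedbank split evenly).
#' @param season_year calendar year simulated.
#' @param temp_mean,temp_amplitude annual air-temperature mean and
#'   amplitude, degrees C.
#' @param temp_phase_doy day of year of the warm peak.
#' @param temp_noise_sd day-level Gaussian noise sd, degrees C.
#' @param diurnal_half_range half-range used for daily min/max, degrees C.
#' @param soil_lag_days,soil_smooth_days soil temperature = air temperature
#'   smoothed over `soil_smooth_days` and lagged `soil_lag_days`.
#' @param rain_wet_prob probability a day is wet.
#' @param rain_wet_mean_mm mean rainfall on wet days, mm.
#' @param true_model list `(kind, a, b, c)`: the expected cumulative
#'   fraction of the seedbank emerged as a function of thermal time.
#' @param seedbank_n germinable seeds per site.
#' @param base_temp,direction,anchor_month_day thermal-time convention;
#'   defaults: cooling degree days below 21 C from June 21.
#' @return a `"sim_config"` list.
#' @export
sim_config <- function(seed = 1L, n_sites = 1L, n_plots = 1L,
                       season_year = 2019L,
                       temp_mean = 15.5, temp_amplitude = 11,
                       temp_phase_doy = 200, temp_noise_sd = 2,
                       diurnal_half_range = 5,
                       soil_lag_days = 2L, soil_smooth_days = 3L,
                       rain_wet_prob = 0.3, rain_wet_mean_mm = 9,
                       true_model = list(kind = "gompertz", a = 0.485,
                                         b = 12.141, c = 0.081),
                       seedbank_n = 10000L,
                       base_temp = 21, direction = "below_base",
                       anchor_month_day = "06-21") {
  stopifnot(seedbank_n > 0, n_sites >= 1, n_plots >= 1,
            rain_wet_prob >= 0, rain_wet_prob <= 1,
            temp_amplitude >= 0,
            true_model$kind %in% c("gompertz", "saturating_exp"))
  cfg <- list(seed = as.integer(seed), n_sites = as.integer(n_sites),
              n_plots = as.integer(n_plots),
              season_year = as.integer(season_year),
              temp_mean = temp_mean, temp_amplitude = temp_amplitude,
              temp_phase_doy = temp_phase_doy, temp_noise_sd = temp_noise_sd,
              diurnal_half_range = diurnal_half_range,
              soil_lag_days = as.integer(soil_lag_days),
              soil_smooth_days = as.integer(soil_smooth_days),
              rain_wet_prob = rain_wet_prob,
              rain_wet_mean_mm = rain_wet_mean_mm,
              true_model = true_model, seedbank_n = as.integer(seedbank_n),
              base_temp = base_temp, direction = direction,
              anchor_month_day = anchor_month_day)
  class(cfg) <- "sim_config"
  cfg
}

sim_anchor <- function(config)
  as.Date(sprintf("%d-%s", config$season_year, config$anchor_month_day))

#' Simulate daily weather with a known seasonal cycle
#'
#' Daily mean air temperature follows
#' `mean + amplitude * cos(2 * pi * (doy - phase) / 365)` plus Gaussian
#' day-level noise; min/max are the mean minus/plus the diurnal half-range;
#' soil temperature at 5 cm is a trailing moving average of air temperature
#' lagged by the configured coupling; rainfall is a Bernoulli wet-day
#' indicator times a Gamma draw with the configured wet-day mean. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [weather_series()] covering the whole season year, all sites.
#' @export
simulate_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dates <- seq(as.Date(sprintf("%d-01-01", config$season_year)),
               as.Date(sprintf("%d-12-31", config$season_year)), by = "day")
  doy <- as.integer(format(dates, "%j"))
  nd <- length(dates)
  out <- lapply(seq_len(config$n_sites), function(s) {
    clim <- config$temp_mean + config$temp_amplitude *
      cos(2 * pi * (doy - config$temp_phase_doy) / 365)
    t_air <- clim + stats::rnorm(nd, sd = config$temp_noise_sd)
    k <- config$soil_smooth_days
    sm <- as.numeric(stats::filter(t_air, rep(1 / k, k), sides = 1))
    sm[seq_len(k - 1)] <- cumsum(t_air[seq_len(k - 1)]) / seq_len(k - 1)
    lag <- config$soil_lag_days
    t_soil <- if (lag > 0) c(sm[rep(1, lag)], sm[seq_len(nd - lag)]) else sm
    wet <- stats::rbinom(nd, 1, config$rain_wet_prob)
    amount <- stats::rgamma(nd, shape = 2, scale = config$rain_wet_mean_mm / 2)
    data.frame(site_id = sprintf("site_%02d", s), date = dates,
               t_air_mean = t_air,
               t_air_min = t_air - config$diurnal_half_range,
               t_air_max = t_air + config$diurnal_half_range,
               t_soil_5cm = t_soil,
               rainfall = wet * amount)
  })
  weather_series(do.call(rbind, out))
}

#' Field monitoring schedule for a season year
#'
#' Weekly visits January 1 through May 31, biweekly June 1 through
#' August 31, weekly September 1 through December 31 — the cadence of the
#' emergence-monitoring protocol.
#'
#' @param season_year calendar year.
#' @return sorted `Date` vector of observation dates.
#' @export
monitoring_schedule <- function(season_year) {
  y <- season_year
  s1 <- seq(as.Date(sprintf("%d-01-07", y)), as.Date(sprintf("%d-05-31", y)),
            by = 7)
  s2 <- seq(max(s1) + 14, as.Date(sprintf("%d-08-31", y)), by = 14)
  s3 <- seq(max(s2) + 7, as.Date(sprintf("%d-12-31", y)), by = 7)
  c(s1, s2, s3)
}

#' Simulate dated seedling counts from a true emergence model
#'
#' Computes the thermal-time accumulation for each simulated site, reads
#' the true model's expected cumulative seedbank fraction at each scheduled
#' visit, and draws the interval counts multinomially over the season: each
#' of the `seedbank_n / n_plots` seeds in a plot emerges in at most one
#' interval, with interval probabilities `F(t_i) - F(t_{i-1})` (drawn
#' sequentially as `Binomial(N - emerged so far, dp_i / (1 - F_{i-1}))`).
#' A seed counted once is gone — the observation model of exhaustive
#' count-and-remove monitoring. Visits before the thermal-time anchor have
#' `F = 0`. Rainfall does not modulate emergence: the truth is
#' thermal-time-only by design.
#'
#' @param weather a [weather_series()] from [simulate_weather()] (or real
#'   data with the same columns).
#' @param config the [sim_config()] used.
#' @param schedule optional observation dates; default
#'   [monitoring_schedule()] for the season year.
#' @return an [emergence_records()] data frame with attributes `truth`
#'   (the true parameter list) and `seedbank_n`.
#' @export
simulate_emergence <- function(weather, config, schedule = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  if (is.null(schedule)) schedule <- monitoring_schedule(config$season_year)
  schedule <- sort(as.Date(schedule))
  if (min(schedule) < min(weather$date) || max(schedule) > max(weather$date))
    stop("monitoring schedule extends outside the weather span")
  anchor <- sim_anchor(config)
  tm <- config$true_model
  f <- model_fun(tm$kind)
  n_per_plot <- config$seedbank_n %/% config$n_plots
  recs <- lapply(unique(weather$site_id), function(site) {
    w <- weather[weather$site_id == site, , drop = FALSE]
    tts <- thermal_time(w, base_temp = config$base_temp,
                        anchor_date = anchor, direction = config$direction)
    cdd <- vapply(schedule, function(d)
      if (d < anchor) NA_real_ else thermal_time_at_date(tts, d, site = site),
      numeric(1))
    Fcum <- ifelse(is.na(cdd), 0, f(ifelse(is.na(cdd), 0, cdd),
                                    tm$a, tm$b, tm$c))
    dp <- pmax(0, diff(c(0, Fcum)))
    Fprev <- c(0, Fcum[-length(Fcum)])
    do.call(rbind, lapply(seq_len(config$n_plots), function(p) {
      remaining <- n_per_plot
      emerged_frac <- 0
      counts <- integer(length(dp))
      for (i in seq_along(dp)) {
        cond_p <- if (Fprev[i] >= 1) 0 else dp[i] / (1 - Fprev[i])
        counts[i] <- stats::rbinom(1, remaining, min(1, cond_p))
        remaining <- remaining - counts[i]
      }
      data.frame(site_id = site, plot_id = sprintf("plot_%d", p),
                 date = schedule, new_seedlings = counts)
    }))
  })
  out <- emergence_records(do.call(rbind, recs))
  attr(out, "truth") <- tm
  attr(out, "seedbank_n") <- config$seedbank_n
  out
}

#' Simulate a predictor matrix with one correlated candidate
#'
#' Stand-in for a panel of screened environmental parameters: one
#' designated predictor is constructed with a chosen population correlation
#' to the response; the remaining `k - 1` are independent noise. Used to
#' verify that the Pearson screen ranks the true driver first.
#'
#' @param config a [sim_config()] (only the seed is used).
#' @param k number of candidate predictors (default 25).
#' @param n observations (default 200).
#' @param target_r population correlation of the designated predictor with
#'   the response, in \[-1, 1\] (default 0.9).
#' @return list with `predictors` (data frame `env_01` ... `env_k`),
#'   `response`, and `designated` (the correlated predictor's name,
#'   always `"env_01"`).
#' @export
simulate_predictors <- function(config, k = 25, n = 200, target_r = 0.9) {
  stopifnot(abs(target_r) <= 1, k >= 1, n >= 3)
  set.seed(config$seed + 2L)
  response <- stats::rnorm(n)
  z <- stats::rnorm(n)
  designated <- target_r * response + sqrt(1 - target_r^2) * z
  preds <- matrix(stats::rnorm(n * k), nrow = n)
  preds[, 1] <- designated
  colnames(preds) <- sprintf("env_%02d", seq_len(k))
  list(predictors = as.data.frame(preds), response = response,
       designated = "env_01")
}
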