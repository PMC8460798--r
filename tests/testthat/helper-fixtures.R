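# Fixtures built in code: small weather series, thermal-time series and
# emergence curves with known arithmetic.

make_weather <- function(temps, start = as.Date("2019-06-21"),
                         site = "a", ...) {
  extra <- list(...)
  df <- data.frame(site_id = site, date = start + seq_along(temps) - 1,
                   t_air_mean = temps)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  weather_series(df)
}

# an emergence_curve object directly from dates/counts/cdd
toy_curve <- function(dates, counts, cdd = seq_along(dates)) {
  dates <- as.Date(dates)
  cum <- cumsum(counts)
  structure(
    data.frame(date = dates, cdd = cdd, count = as.integer(counts),
               cum_count = cum, cum_fraction = cum / sum(counts)),
    site_id = "toy", season_year = as.integer(format(dates[1], "%Y")),
    yearly_total = sum(counts), anchor_date = dates[1] - 1,
    class = c("emergence_curve", "data.frame"))
}

# one simulate -> accumulate -> fit replicate on the seedbank scale;
# returns fitted coefficients
recover_once <- function(seed, true_model = NULL) {
  cfg <- if (is.null(true_model)) sim_config(seed = seed)
         else sim_config(seed = seed, true_model = true_model)
  w <- simulate_weather(cfg)
  r <- simulate_emergence(w, cfg)
  tts <- thermal_time(w, base_temp = cfg$base_temp,
                      anchor_date = sprintf("%d-06-21", cfg$season_year))
  agg <- tapply(r$new_seedlings, format(r$date), sum)
  d <- as.Date(names(agg)); o <- order(d)
  cum <- cumsum(as.integer(agg[o])) / cfg$seedbank_n
  dd <- d[o]
  keep <- dd >= as.Date(sprintf("%d-06-21", cfg$season_year))
  cdd <- thermal_time_at_date(tts, dd[keep])
  coef(fit_emergence(data.frame(cdd = cdd, cum_fraction = cum[keep]),
                     cfg$true_model$kind))
}
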