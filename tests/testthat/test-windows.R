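test_that("peak window maximizes the captured share, earliest on ties", {
  d0 <- as.Date("2019-09-02")
  # uniform weekly emergence over 10 weeks, 4-week window -> share 0.4
  cv <- toy_curve(d0 + 7 * (0:9), rep(3, 10))
  pw <- peak_window(cv, weeks = 4)
  expect_equal(pw$share, 0.4)
  expect_equal(pw$start_date, d0)

  # all emergence in one week
  cv <- toy_curve(d0 + 7 * (0:5), c(0, 0, 30, 0, 0, 0))
  expect_equal(peak_window(cv, weeks = 4)$share, 1)

  # weekly counts 1 5 5 5 5 1 -> window over obs 2..5, share 20/22
  cv <- toy_curve(d0 + 7 * (0:5), c(1, 5, 5, 5, 5, 1))
  pw <- peak_window(cv, weeks = 4)
  expect_equal(pw$share, 20 / 22)
  expect_equal(pw$start_date, d0 + 7)

  expect_error(peak_window(toy_curve(d0 + c(0, 7), c(1, 1)), weeks = 4),
               "shorter")
})

test_that("peak window equals the exhaustive scan on random curves", {
  set.seed(81)
  for (i in 1:30) {
    n <- sample(8:20, 1)
    gaps <- sample(c(7, 14), n - 1, replace = TRUE)
    dates <- as.Date("2019-08-01") + c(0, cumsum(gaps))
    counts <- rpois(n, 5)
    counts[1] <- counts[1] + 1  # non-zero total
    cv <- toy_curve(dates, counts)
    weeks <- sample(2:5, 1)
    if (as.integer(max(dates) - min(dates)) + 1 < weeks * 7) next
    pw <- peak_window(cv, weeks = weeks)
    brute <- max(vapply(seq_along(dates), function(j) {
      s <- dates[j]
      sum(counts[dates >= s & dates <= s + weeks * 7 - 1])
    }, numeric(1))) / sum(counts)
    expect_equal(pw$share, brute)
  }
})

test_that("peak-window weather summaries cover the window days", {
  d0 <- as.Date("2019-09-01")
  w <- make_weather(rep(18, 80), start = d0,
                    t_soil_5cm = rep(16, 80), rainfall = rep(2, 80))
  cv <- toy_curve(d0 + 7 * (0:8), rep(2, 9))
  pw <- peak_window(cv, weather = w, weeks = 4)
  expect_equal(pw$summaries$mean_air_temp, 18)
  expect_equal(pw$summaries$mean_soil_temp, 16)
  expect_equal(pw$summaries$total_rainfall, 2 * 28)
})

test_that("rapid-change weeks summarize across site-years", {
  s1 <- data.frame(week = 36:45, share = rep(0.1, 10))
  one <- rapid_change_weeks(list(s1))
  expect_equal(one$summary$median, s1$share)

  two <- rapid_change_weeks(list(s1, s1))
  expect_equal(two$summary$p25, two$summary$p75)

  # three site-years peaked at weeks 40-43 by construction
  mk <- function(eps) {
    sh <- rep(0.02, 15); names(sh) <- 33:47
    sh[as.character(40:43)] <- 0.175 + eps
    data.frame(week = 33:47, share = as.numeric(sh / sum(sh)))
  }
  res <- rapid_change_weeks(list(mk(0), mk(0.01), mk(-0.01)), span_weeks = 4)
  expect_equal(res$week_range, c(40, 43))

  # permutation of site-years leaves the summaries unchanged
  l <- list(mk(0), mk(0.01), mk(-0.01))
  expect_equal(rapid_change_weeks(l)$summary,
               rapid_change_weeks(rev(l))$summary)
})

test_that("trailing rolling means behave like hand-computed windows", {
  d0 <- as.Date("2019-09-01")
  w <- make_weather(rep(20, 10), start = d0, t_soil_5cm = rep(18, 10),
                    rainfall = c(0, 0, 0, 0, 0, 0, 7, 0, 0, 0))
  roll <- rolling_edaphic(w, 7)
  expect_true(all(roll$t_soil_5cm_roll[7:10] == 18))
  expect_true(all(is.na(roll$t_soil_5cm_roll[1:6])))
  expect_equal(roll$rainfall_roll[7], 1)

  w2 <- make_weather(rep(20, 7), start = d0, t_soil_5cm = 10:16,
                     rainfall = rep(0, 7))
  expect_equal(rolling_edaphic(w2, 7)$t_soil_5cm_roll[7], 13)

  # affine rescaling commutes with the rolling mean
  w3 <- make_weather(rep(20, 7), start = d0, t_soil_5cm = 1.8 * (10:16) + 32)
  expect_equal(rolling_edaphic(w3, 7, "t_soil_5cm")$t_soil_5cm_roll[7],
               1.8 * 13 + 32)
})

test_that("edaphic summaries report across-year means and spread", {
  d0 <- as.Date("2019-09-01")
  w19 <- make_weather(rep(20, 60), start = d0, t_soil_5cm = rep(18, 60),
                      rainfall = rep(1, 60))
  w20 <- make_weather(rep(20, 60), start = d0, t_soil_5cm = rep(20, 60),
                      rainfall = rep(3, 60))
  es <- edaphic_summary(list(w19, w20), list(c(d0 + 20, d0 + 40)))
  expect_equal(unname(es$mean["t_soil_5cm_roll"]), 19)
  expect_equal(unname(es$spread["t_soil_5cm_roll"]), sd(c(18, 20)))
  expect_true(all(es$spread >= 0))

  single <- edaphic_summary(w19, c(d0 + 20, d0 + 40))
  expect_true(is.na(single$spread["t_soil_5cm_roll"]))
  expect_error(edaphic_summary(w19, c(d0, d0 + 2)), "no complete")
})

test_that("day/night means split sub-daily readings at fixed clock hours", {
  hrs <- seq(0, 23.75, by = 0.25)
  tt <- as.POSIXct("2019-10-01 00:00:00", tz = "UTC") + hrs * 3600
  expect_equal(day_night_means(tt, rep(15, length(tt))),
               c(day = 15, night = 15))
  v <- ifelse(hrs >= 7 & hrs < 19, 20, 10)
  expect_equal(day_night_means(tt, v), c(day = 20, night = 10))
  # diurnal sinusoid peaking at 14:00: day mean above, night below
  v2 <- 15 + 5 * cos(2 * pi * (hrs - 14) / 24)
  dn <- day_night_means(tt, v2)
  expect_gt(dn["day"], 15)
  expect_lt(dn["night"], 15)
  expect_error(day_night_means(as.Date("2019-10-01"), 15), "POSIXct")
})
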