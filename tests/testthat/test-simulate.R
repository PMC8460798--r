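test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 11)
  w1 <- simulate_weather(cfg); w2 <- simulate_weather(cfg)
  expect_identical(w1, w2)
  r1 <- simulate_emergence(w1, cfg); r2 <- simulate_emergence(w2, cfg)
  expect_identical(r1, r2)
  p1 <- simulate_predictors(cfg); p2 <- simulate_predictors(cfg)
  expect_identical(p1, p2)
})

test_that("zero-noise weather is the exact seasonal cosine", {
  cfg <- sim_config(seed = 1, temp_noise_sd = 0)
  w <- simulate_weather(cfg)
  doy <- as.integer(format(w$date, "%j"))
  expect_equal(w$t_air_mean,
               cfg$temp_mean + cfg$temp_amplitude *
                 cos(2 * pi * (doy - cfg$temp_phase_doy) / 365),
               tolerance = 1e-12)
  # on the phase day the temperature is mean + amplitude
  expect_equal(w$t_air_mean[doy == cfg$temp_phase_doy],
               cfg$temp_mean + cfg$temp_amplitude)
  expect_true(all(w$t_air_min <= w$t_air_mean & w$t_air_mean <= w$t_air_max))
  expect_true(all(w$rainfall >= 0))
})

test_that("wet-day frequency matches the configured probability", {
  cfg <- sim_config(seed = 8, n_sites = 30)  # 30 x 365 = 10,950 indicators
  w <- simulate_weather(cfg)
  expect_lt(abs(mean(w$rainfall > 0) - 0.3), 0.01)
})

test_that("season totals follow the truth asymptote binomially", {
  cfg <- sim_config(seed = 21, seedbank_n = 1000)
  w <- simulate_weather(cfg)
  r <- simulate_emergence(w, cfg)
  total <- sum(r$new_seedlings)
  sd3 <- 3 * sqrt(1000 * 0.485 * 0.515)
  expect_lt(abs(total - 485), sd3)
  # conservation: never more counts than seeds, cumulative non-decreasing
  expect_lte(total, 1000)
  expect_true(all(diff(cumsum(r$new_seedlings)) >= 0))
})

test_that("intervals with a flat truth curve produce no seedlings", {
  cfg <- sim_config(seed = 4)
  w <- simulate_weather(cfg)
  r <- simulate_emergence(w, cfg)
  # before the anchor the truth is identically zero
  expect_true(all(r$new_seedlings[r$date < as.Date("2019-06-21")] == 0))
})

test_that("the schedule must lie inside the weather span", {
  cfg <- sim_config(seed = 4)
  w <- simulate_weather(cfg)
  expect_error(
    simulate_emergence(w, cfg, schedule = as.Date("2020-03-01") + 7 * (0:5)),
    "outside the weather span")
})

test_that("recovery error shrinks with seedbank size", {
  err_at <- function(n, seed) {
    est <- recover_once_n(seed, n)
    max(abs(est - c(0.485, 12.141, 0.081)) / c(0.485, 12.141, 0.081))
  }
  recover_once_n <- function(seed, n) {
    cfg <- sim_config(seed = seed, seedbank_n = n)
    w <- simulate_weather(cfg)
    r <- simulate_emergence(w, cfg)
    tts <- thermal_time(w, anchor_date = "2019-06-21")
    agg <- tapply(r$new_seedlings, format(r$date), sum)
    d <- as.Date(names(agg)); o <- order(d)
    cum <- cumsum(as.integer(agg[o])) / n
    dd <- d[o]; keep <- dd >= as.Date("2019-06-21")
    cdd <- thermal_time_at_date(tts, dd[keep])
    coef(fit_emergence(data.frame(cdd = cdd, cum_fraction = cum[keep]),
                       "gompertz"))
  }
  small <- vapply(1:8, function(i) err_at(500 + i, 1000), numeric(1))
  large <- vapply(1:8, function(i) err_at(500 + i, 100000), numeric(1))
  expect_lt(median(large), median(small))
})

test_that("the designated predictor dominates the screen", {
  sp <- simulate_predictors(sim_config(seed = 2), k = 5, n = 50, target_r = 1)
  scr <- pearson_screen(sp$predictors, sp$response)
  expect_equal(scr$predictor[1], sp$designated)
  expect_equal(scr$r[1], 1, tolerance = 1e-12)

  # |r| shrinks toward zero for an uncorrelated predictor as n grows
  lone <- simulate_predictors(sim_config(seed = 3), k = 1, n = 5000,
                              target_r = 0)
  expect_lt(abs(pearson_screen(lone$predictors, lone$response)$r), 0.05)

  # target_r = 0.9, n = 200: ranked first in (at least) 18 of 20 replicates
  hits <- sum(vapply(1:20, function(i) {
    sp <- simulate_predictors(sim_config(seed = 100 + i))
    pearson_screen(sp$predictors, sp$response)$predictor[1] == sp$designated
  }, logical(1)))
  expect_gte(hits, 18)
})
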