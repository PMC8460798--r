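# printed-parameter sets used throughout: early-season Gompertz and
# full-season saturating exponential
G <- list(a = 0.485, b = 12.141, c = 0.081)
S <- list(a = 0.01275, b = 0.9220, c = 0.004)

test_that("model evaluation matches direct arithmetic", {
  expect_equal(gompertz(0, G$a, G$b, G$c), 0.485 * exp(-12.141),
               tolerance = 1e-12)
  expect_equal(gompertz(30, G$a, G$b, G$c),
               0.485 * exp(-12.141 * exp(-0.081 * 30)), tolerance = 1e-12)
  expect_equal(gompertz(30, G$a, G$b, G$c), 0.1666, tolerance = 1e-3)
  expect_equal(gompertz(1e4, G$a, G$b, G$c), 0.485, tolerance = 1e-9)

  expect_equal(saturating_exp(0, S$a, S$b, S$c), -0.01275)
  expect_equal(saturating_exp(1e9, S$a, S$b, S$c), 0.90925, tolerance = 1e-12)
  expect_equal(saturating_exp(439, S$a, S$b, S$c), 0.750, tolerance = 1e-3)
})

test_that("noiseless synthetic points are recovered essentially exactly", {
  cdd_g <- seq(0, 120, length.out = 50)
  fit_g <- fit_emergence(
    data.frame(cdd = cdd_g, cum_fraction = gompertz(cdd_g, G$a, G$b, G$c)),
    "gompertz")
  expect_lt(max(abs(coef(fit_g) - unlist(G)) / unlist(G)), 1e-4)
  expect_equal(fit_g$metrics$r2, 1, tolerance = 1e-8)

  cdd_s <- seq(0, 1200, length.out = 50)
  fit_s <- fit_emergence(
    data.frame(cdd = cdd_s,
               cum_fraction = saturating_exp(cdd_s, S$a, S$b, S$c)),
    "saturating_exp")
  expect_lt(max(abs(coef(fit_s) - unlist(S)) / unlist(S)), 1e-4)
})

test_that("degenerate and undersized inputs error instead of fitting", {
  expect_error(
    fit_emergence(data.frame(cdd = 1:10, cum_fraction = rep(0.5, 10)),
                  "gompertz"),
    "degenerate|constant")
  expect_error(
    fit_emergence(data.frame(cdd = 1:3, cum_fraction = c(.1, .2, .3)),
                  "gompertz"),
    "at least 4")
  expect_error(
    fit_emergence(data.frame(cdd = rep(2, 5), cum_fraction = runif(5)),
                  "gompertz"),
    "identical")
})

test_that("benchmark inversion is the exact inverse of evaluation", {
  m_s <- emergence_model("saturating_exp", S$a, S$b, S$c)
  # closed form: cdd = -log(1 - (target + a) / b) / c
  expect_equal(cdd_at_fraction(m_s, 0.75),
               -log(1 - (0.75 + S$a) / S$b) / S$c, tolerance = 1e-8)
  expect_equal(cdd_at_fraction(m_s, 0.75), 439.0175, tolerance = 1e-4)
  expect_error(cdd_at_fraction(m_s, 0.95), "asymptote")

  m_g <- emergence_model("gompertz", G$a, G$b, G$c)
  expect_equal(cdd_at_fraction(m_g, gompertz(100, G$a, G$b, G$c)), 100,
               tolerance = 1e-6)
})

test_that("both families are strictly increasing and invertible on cdd >= 0", {
  set.seed(42)
  for (i in 1:25) {
    a <- runif(1, 0.05, 1.5); b <- runif(1, 0.5, 20); c <- runif(1, 0.005, 0.2)
    kind <- if (i %% 2) "gompertz" else "saturating_exp"
    m <- emergence_model(kind, a, b, c)
    grid <- seq(0, 1500, length.out = 400)
    y <- predict(m, cdd = grid)
    expect_true(all(diff(y) >= 0))
    # strict increase wherever the curve is not numerically saturated
    lo_hi <- predict(m, cdd = c(0, 1e9))
    active <- y[-length(y)] < lo_hi[1] + 0.99 * diff(lo_hi)
    expect_true(all(diff(y)[active] > 0))
    # invert(eval(x)) = x within 1e-6 degree days across the attainable
    # range (up to 99.9% of the rise; beyond that the curve is flat to
    # machine precision and no inverse is numerically defined)
    x999 <- cdd_at_fraction(m, lo_hi[1] + 0.999 * diff(lo_hi))
    xs <- runif(4, 1, x999)
    ys <- predict(m, cdd = xs)
    expect_equal(cdd_at_fraction(m, ys), xs, tolerance = 1e-6)
  }
})

test_that("Gompertz inflection matches the numeric second derivative", {
  m <- emergence_model("gompertz", G$a, G$b, G$c)
  infl <- gompertz_inflection(m)
  expect_equal(unname(infl["cdd"]), log(G$b) / G$c)
  expect_equal(unname(infl["value"]), G$a / exp(1))
  # numeric second derivative changes sign at the closed-form inflection
  h <- 1e-3
  d2 <- function(x) (gompertz(x + h, G$a, G$b, G$c) -
                     2 * gompertz(x, G$a, G$b, G$c) +
                     gompertz(x - h, G$a, G$b, G$c)) / h^2
  expect_gt(d2(infl["cdd"] - 1), 0)
  expect_lt(d2(infl["cdd"] + 1), 0)
  expect_lt(abs(d2(infl["cdd"])), abs(d2(infl["cdd"] - 1)) / 50)
})

test_that("fit methods expose the usual modelling surface", {
  cdd <- seq(0, 120, length.out = 40)
  set.seed(3)
  y <- pmax(0, gompertz(cdd, G$a, G$b, G$c) + rnorm(40, sd = 0.004))
  fit <- fit_emergence(data.frame(cdd = cdd, cum_fraction = y), "gompertz")
  expect_s3_class(fit, "emergence_fit")
  expect_named(coef(fit), c("a", "b", "c"))
  expect_equal(length(residuals(fit)), 40)
  expect_equal(fitted(fit) + residuals(fit), y, tolerance = 1e-12)
  expect_equal(dim(vcov(fit)), c(3, 3))
  s <- summary(fit)
  expect_s3_class(s, "summary.emergence_fit")
  expect_output(print(fit), "Gompertz")
  sims <- simulate(fit, nsim = 3, seed = 1, seedbank_n = 5000)
  expect_equal(dim(sims), c(40, 3))
  expect_true(all(sims >= 0))
})

test_that("noisy parameter recovery is unbiased with a and c well resolved", {
  # 20 seeded replicates through the full simulator at seedbank 10,000;
  # the displacement b carries a few-percent noise floor (see vignette),
  # so assert exact recovery only where the data can support it
  errs <- t(vapply(1:20, function(i) {
    est <- recover_once(3000 + i)
    abs(est - c(G$a, G$b, G$c)) / c(G$a, G$b, G$c)
  }, numeric(3)))
  expect_true(all(errs[, 1] < 0.05))        # asymptote a
  expect_true(all(errs[, 3] < 0.05))        # rate c
  expect_lt(median(errs[, 2]), 0.05)        # displacement b: median only
})
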