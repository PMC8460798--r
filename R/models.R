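#' Emergence model families
#'
#' Two monotone saturating curves map thermal time (degree days) to a
#' cumulative emergence fraction.
#'
#' `gompertz()` is the asymmetric sigmoid
#' \deqn{y = a \, e^{-b \, e^{-c \, x}}}{y = a * exp(-b * exp(-c * x))}
#' with upper asymptote `a`, x-displacement `b` and rate `c`; it models the
#' early-season (0-50% of yearly total) portion of the curve. Its inflection
#' sits at `x = log(b)/c` with value `a/e`.
#'
#' `saturating_exp()` is the saturating exponential borrowed from ruminal
#' feed-degradation kinetics,
#' \deqn{y = -a + b (1 - e^{-c x})}{y = -a + b * (1 - exp(-c * x))},
#' with value `-a` at `x = 0` and asymptote `-a + b`; it models the full
#' yearly-cumulative curve.
#'
#' Emergence is a fraction in \[0, 1\] throughout; percent belongs to the
#' reporting boundary only.
#'
#' @param cdd thermal time, degree days (`>= 0`).
#' @param a,b,c model parameters (see Details).
#' @return predicted emergence fraction(s).
#' @examples
#' gompertz(30, 0.485, 12.141, 0.081)        # ~0.167
#' saturating_exp(439, 0.01275, 0.9220, 0.004)  # ~0.750
#' @export
gompertz <- function(cdd, a, b, c) a * exp(-b * exp(-c * cdd))

#' @rdname gompertz
#' @export
saturating_exp <- function(cdd, a, b, c) -a + b * (1 - exp(-c * cdd))

model_fun <- function(kind) {
  switch(kind, gompertz = gompertz, saturating_exp = saturating_exp,
         stop("unknown model kind: ", kind))
}

# value at cdd = 0 and the large-cdd asymptote, as a (lo, hi) range
model_range <- function(kind, p) {
  a <- p[["a"]]; b <- p[["b"]]; c <- p[["c"]]
  switch(kind,
         gompertz = c(a * exp(-b), a),
         saturating_exp = c(-a, -a + b))
}

#' Construct an emergence-model object from known parameters
#'
#' Wraps a parameter triple as a minimal `"emergence_fit"` so that
#' prediction and inversion work on published or simulated-truth parameters
#' without refitting.
#'
#' @param kind `"gompertz"` or `"saturating_exp"`.
#' @param a,b,c parameters on the fraction scale.
#' @return an `"emergence_fit"` object (no data, no fit metrics).
#' @examples
#' m <- emergence_model("saturating_exp", a = 0.01275, b = 0.9220, c = 0.004)
#' cdd_at_fraction(m, 0.75)
#' @export
emergence_model <- function(kind = c("gompertz", "saturating_exp"), a, b, c) {
  kind <- match.arg(kind)
  structure(list(kind = kind, coefficients = c(a = a, b = b, c = c),
                 converged = NA, n = 0L, metrics = NULL, data = NULL,
                 vcov = NULL, call = sys.call()),
            class = "emergence_fit")
}

#' Fit an emergence model by multi-start nonlinear least squares
#'
#' Fits [gompertz()] or [saturating_exp()] to (thermal time, cumulative
#' fraction) points by unweighted least squares. When no starting values are
#' given, a deterministic multi-start grid is tried — `a` in \{0.5, 1\}
#' (the asymptote candidates), `b` from the log-displacement heuristic
#' `b = -log(y_first / a)`, `c` in \{0.001, 0.01, 0.1\} — and the converged
#' fit with the smallest residual sum of squares wins, so fits are
#' reproducible. Optimisation is Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) with positivity bounds on `b` and `c`.
#'
#' Cumulative observations are serially dependent; like the field analyses
#' this fit targets, the least-squares criterion ignores that
#' autocorrelation. Metrics (R-squared, MAE, MSLE) are computed on the
#' fitted points.
#'
#' @param x an `"emergence_curve"`, or a data frame with columns `cdd` and
#'   `cum_fraction` (or `fraction`/`y`).
#' @param kind `"gompertz"` or `"saturating_exp"`.
#' @param init optional named start `c(a=, b=, c=)`; skips the grid.
#' @param lower,upper optional bounds, named like `init`.
#' @param ... unused.
#' @return an object of class `"emergence_fit"`: coefficients, covariance,
#'   convergence flag, data, fitted values and `metrics` (`r2`, `mae`,
#'   `msle`). Methods: `print`, `summary`, `coef`, `vcov`, `predict`,
#'   `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' cdd <- seq(0, 120, length.out = 50)
#' y <- gompertz(cdd, 0.485, 12.141, 0.081)
#' fit <- fit_emergence(data.frame(cdd = cdd, cum_fraction = y), "gompertz")
#' coef(fit)
#' @export
fit_emergence <- function(x, kind = c("gompertz", "saturating_exp"),
                          init = NULL, lower = NULL, upper = NULL, ...) {
  kind <- match.arg(kind)
  df <- as.data.frame(x)
  ycol <- intersect(c("cum_fraction", "fraction", "y"), names(df))[1]
  if (is.na(ycol) || !"cdd" %in% names(df))
    stop("x must provide columns `cdd` and `cum_fraction` (or `fraction`/`y`)")
  cdd <- as.numeric(df$cdd)
  y <- as.numeric(df[[ycol]])
  ok <- is.finite(cdd) & is.finite(y)
  cdd <- cdd[ok]; y <- y[ok]
  n <- length(y)
  if (n < 4) stop("need at least 4 points to fit a 3-parameter model")
  if (any(cdd < 0)) stop("negative thermal-time values")
  if (length(unique(cdd)) < 2) stop("all thermal-time values identical")
  if (stats::sd(y) == 0)
    stop("degenerate input: response is constant; model unidentifiable")

  starts <- if (!is.null(init)) list(as.list(init)) else start_grid(kind, cdd, y)
  if (is.null(lower))
    lower <- c(a = if (kind == "gompertz") 1e-8 else -1, b = 1e-8, c = 1e-8)
  if (is.null(upper)) upper <- c(a = Inf, b = Inf, c = Inf)

  form <- switch(kind,
    gompertz = y ~ a * exp(-b * exp(-c * cdd)),
    saturating_exp = y ~ -a + b * (1 - exp(-c * cdd)))
  dat <- data.frame(cdd = cdd, y = y)

  best <- NULL; best_rss <- Inf
  best_any <- NULL; best_any_rss <- Inf
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = dat, start = s,
        lower = lower[c("a", "b", "c")], upper = upper[c("a", "b", "c")],
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    conv <- isTRUE(fit$convInfo$isConv)
    if (rss < best_any_rss) { best_any <- fit; best_any_rss <- rss }
    if (conv && rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best)) {
    if (is.null(best_any))
      stop("no start converged for ", kind, " fit")
    p <- stats::coef(best_any)
    stop(sprintf(paste0("no start converged for %s fit; best non-converged ",
                        "parameters a=%.6g b=%.6g c=%.6g (rss %.3g)"),
                 kind, p["a"], p["b"], p["c"], best_any_rss))
  }

  p <- stats::coef(best)
  pred <- model_fun(kind)(cdd, p["a"], p["b"], p["c"])
  vc <- tryCatch(stats::vcov(best), error = function(e) NULL)
  structure(list(
    kind = kind,
    coefficients = p,
    vcov = vc,
    converged = TRUE,
    n = n,
    data = dat,
    fitted.values = pred,
    residuals = y - pred,
    metrics = list(r2 = r_squared(y, pred),
                   mae = mae(y, pred),
                   msle = msle(y, pred)),
    call = match.call()),
    class = "emergence_fit")
}

start_grid <- function(kind, cdd, y) {
  starts <- list()
  if (kind == "gompertz") {
    y1 <- max(min(y[y > 0], na.rm = TRUE), 1e-8)
    for (a in c(0.5, 1.0)) {
      b0 <- max(-log(min(y1 / a, 0.999)), 0.1)
      for (c0 in c(0.001, 0.01, 0.1))
        starts[[length(starts) + 1L]] <- list(a = a, b = b0, c = c0)
    }
  } else {
    ymax <- max(y)
    for (b in c(max(ymax, 0.1), 1.0))
      for (c0 in c(0.001, 0.01, 0.1))
        starts[[length(starts) + 1L]] <- list(a = 0.01, b = b, c = c0)
  }
  starts
}

#' @export
coef.emergence_fit <- function(object, ...) object$coefficients

#' @export
vcov.emergence_fit <- function(object, ...) object$vcov

#' @export
fitted.emergence_fit <- function(object, ...) object$fitted.values

#' @export
residuals.emergence_fit <- function(object, ...) object$residuals

#' Predict emergence fraction at given thermal times
#'
#' @param object an `"emergence_fit"`.
#' @param newdata data frame with a `cdd` column, or omitted to use the
#'   fitting data.
#' @param cdd alternatively, a numeric vector of degree-day values.
#' @param ... unused.
#' @return predicted cumulative emergence fractions.
#' @export
predict.emergence_fit <- function(object, newdata = NULL, cdd = NULL, ...) {
  if (is.null(cdd)) {
    cdd <- if (!is.null(newdata)) newdata$cdd
           else if (!is.null(object$data)) object$data$cdd
           else stop("supply `newdata` or `cdd`")
  }
  p <- object$coefficients
  model_fun(object$kind)(cdd, p[["a"]], p[["b"]], p[["c"]])
}

#' @export
print.emergence_fit <- function(x, digits = 4, ...) {
  label <- switch(x$kind, gompertz = "Gompertz",
                  saturating_exp = "Saturating-exponential")
  cat(label, "emergence model\n")
  print(signif(x$coefficients, digits))
  if (!is.null(x$metrics))
    cat(sprintf("n = %d, R2 = %.3f, MAE = %.4f, MSLE = %.5f\n",
                x$n, x$metrics$r2, x$metrics$mae, x$metrics$msle))
  invisible(x)
}

#' @export
summary.emergence_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else rep(NA_real_, 3)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se)
  structure(list(kind = object$kind, coefficients = tab, n = object$n,
                 converged = object$converged, metrics = object$metrics,
                 asymptote = model_range(object$kind,
                                         as.list(object$coefficients))[2]),
            class = "summary.emergence_fit")
}

#' @export
print.summary.emergence_fit <- function(x, ...) {
  cat("Kind:", x$kind, "  converged:", x$converged, "\n")
  stats::printCoefmat(x$coefficients, signif.stars = FALSE)
  cat(sprintf("Upper asymptote: %.4f\n", x$asymptote))
  if (!is.null(x$metrics))
    cat(sprintf("Fit (n = %d): R2 = %.4f, MAE = %.4f, MSLE = %.5f\n",
                x$n, x$metrics$r2, x$metrics$mae, x$metrics$msle))
  invisible(x)
}

#' @export
plot.emergence_fit <- function(x, ...,
                               xlab = "Cooling degree days",
                               ylab = "Cumulative emergence (fraction)") {
  if (is.null(x$data)) stop("no data stored in this model object")
  graphics::plot(x$data$cdd, x$data$y, xlab = xlab, ylab = ylab, ...)
  grid_x <- seq(min(x$data$cdd), max(x$data$cdd), length.out = 200)
  graphics::lines(grid_x, predict(x, cdd = grid_x))
  invisible(x)
}

#' Simulate observation-noise replicates from a fitted emergence model
#'
#' Draws seedling counts per observation interval as independent binomials
#' on a seedbank of size `seedbank_n`, with interval probabilities given by
#' the fitted curve's increments at the model's own thermal-time points.
#'
#' @param object an `"emergence_fit"` with stored data.
#' @param nsim number of replicate count series.
#' @param seed optional RNG seed.
#' @param seedbank_n seedbank size per replicate (default 10000).
#' @param ... unused.
#' @return data frame of `nsim` columns of interval counts, one row per
#'   thermal-time point.
#' @export
simulate.emergence_fit <- function(object, nsim = 1, seed = NULL,
                                   seedbank_n = 10000, ...) {
  if (is.null(object$data)) stop("no data stored in this model object")
  if (!is.null(seed)) set.seed(seed)
  f <- predict(object)
  dp <- pmax(0, diff(c(0, f)))
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(dp), seedbank_n, dp)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Thermal time at which a model attains a target emergence fraction
#'
#' Inverts a monotone emergence model by bracketed root-finding
#' ([stats::uniroot()] driven to `|f| < 1e-10`): the unique degree-day value
#' at which the curve equals `target`. This is how benchmark thermal times
#' (e.g. the CDD at 50% or 75% of yearly emergence) are read off a fitted
#' yearly-cumulative model.
#'
#' @param object an `"emergence_fit"` (fitted or from [emergence_model()]).
#' @param target emergence fraction, strictly between the model's value at
#'   zero thermal time and its asymptote.
#' @return degree days (length matches `target`).
#' @examples
#' m <- emergence_model("saturating_exp", 0.01275, 0.9220, 0.004)
#' cdd_at_fraction(m, 0.75)  # ~439 degree days
#' @export
cdd_at_fraction <- function(object, target) {
  stopifnot(inherits(object, "emergence_fit"), is.numeric(target))
  p <- as.list(object$coefficients)
  rng <- model_range(object$kind, p)
  f <- model_fun(object$kind)
  vapply(target, function(tg) {
    if (tg <= rng[1] || tg >= rng[2])
      stop(sprintf(paste0("target %.4f outside attainable range (%.6g at cdd ",
                          "= 0; asymptote %.6g)"), tg, rng[1], rng[2]))
    hi <- 1
    while (f(hi, p$a, p$b, p$c) < tg) {
      hi <- hi * 2
      if (hi > 1e9) stop("target not reached below 1e9 degree days")
    }
    stats::uniroot(function(x) f(x, p$a, p$b, p$c) - tg,
                   lower = 0, upper = hi, tol = 1e-12)$root
  }, numeric(1))
}

#' Inflection point of a Gompertz emergence model
#'
#' Closed form: the curve inflects at `cdd = log(b)/c`, where its value is
#' `a/e` — the thermal time of fastest emergence under the early-season
#' model.
#'
#' @param object an `"emergence_fit"` of kind `"gompertz"`.
#' @return named vector `c(cdd = , value = )`.
#' @export
gompertz_inflection <- function(object) {
  stopifnot(inherits(object, "emergence_fit"), object$kind == "gompertz")
  p <- object$coefficients
  c(cdd = log(p[["b"]]) / p[["c"]], value = p[["a"]] / exp(1))
}
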