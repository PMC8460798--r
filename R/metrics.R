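#' Fit and validation metrics
#'
#' The three statistics used to judge emergence-model fits, on paired
#' observed/predicted series:
#'
#' * `r_squared()`: coefficient of determination,
#'   `1 - SS_res / SS_tot` with the total sum of squares about the observed
#'   mean. Can be negative for models worse than the mean; undefined
#'   (an error) when the observed series is constant.
#' * `mae()`: mean absolute error, in the units of the inputs.
#' * `msle()`: mean squared logarithmic error,
#'   `mean((log1p(observed) - log1p(predicted))^2)`; both series must
#'   exceed -1.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return a single number.
#' @examples
#' r_squared(c(0, 1, 2), c(0, 1, 3))   # 0.5
#' mae(c(0.1, 0.4), c(0.2, 0.1))       # 0.2
#' msle(c(0.5, 0.5), c(0, 0))          # log(1.5)^2
#' @export
r_squared <- function(observed, predicted) {
  check_paired(observed, predicted, min_n = 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("R-squared undefined: observed series is constant")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' @rdname r_squared
#' @export
mae <- function(observed, predicted) {
  check_paired(observed, predicted, min_n = 1)
  mean(abs(observed - predicted))
}

#' @rdname r_squared
#' @export
msle <- function(observed, predicted) {
  check_paired(observed, predicted, min_n = 1)
  if (any(observed <= -1) || any(predicted <= -1))
    stop("MSLE undefined for values <= -1")
  mean((log1p(observed) - log1p(predicted))^2)
}

check_paired <- function(observed, predicted, min_n) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ (",
         length(observed), " vs ", length(predicted), ")")
  if (length(observed) < min_n)
    stop("need at least ", min_n, " paired value(s)")
  if (any(!is.finite(observed)) || any(!is.finite(predicted)))
    stop("non-finite values in paired series")
  invisible(TRUE)
}

#' Screen candidate environmental predictors by Pearson correlation
#'
#' Ranks candidate predictors (e.g. soil temperature, rainfall, light) by
#' the absolute Pearson correlation of each with an emergence response —
#' the exploratory screen that selects the thermal-time driver. The
#' response is typically the per-interval emergence increments ("changes in
#' emergence"); pass a cumulative series with `response_mode =
#' "cumulative"` documented as such. No multiple-testing correction is
#' applied; this is a ranking, not an inference.
#'
#' Zero-variance predictors have undefined correlation; they are kept,
#' flagged, and ranked last.
#'
#' @param predictors data frame or matrix, one column per candidate.
#' @param response numeric vector, same length as the predictor columns.
#' @param response_mode label recorded on the result: `"increments"`
#'   (default) or `"cumulative"`.
#' @return a `"pearson_screen"` data frame with columns `predictor`, `r`,
#'   `abs_r`, `defined`, sorted by `abs_r` descending (undefined last).
#' @examples
#' set.seed(1)
#' x <- data.frame(p1 = rnorm(20), p2 = rnorm(20))
#' pearson_screen(x, 2 * x$p1)
#' @export
pearson_screen <- function(predictors, response,
                           response_mode = c("increments", "cumulative")) {
  response_mode <- match.arg(response_mode)
  predictors <- as.data.frame(predictors)
  n <- length(response)
  if (n < 3) stop("need at least 3 observations to screen")
  bad <- vapply(predictors, function(x) length(x) != n, logical(1))
  if (any(bad))
    stop("predictor length mismatch: ", paste(names(predictors)[bad],
                                              collapse = ", "))
  r <- vapply(predictors, function(x) {
    if (stats::sd(x) == 0 || stats::sd(response) == 0) NA_real_
    else stats::cor(x, response, method = "pearson")
  }, numeric(1))
  out <- data.frame(predictor = names(predictors), r = r, abs_r = abs(r),
                    defined = !is.na(r), row.names = NULL)
  out <- out[order(-out$defined, -out$abs_r), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, response_mode = response_mode,
            class = c("pearson_screen", "data.frame"))
}

#' @export
print.pearson_screen <- function(x, ...) {
  cat("Pearson predictor screen (response:", attr(x, "response_mode"), ")\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}
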