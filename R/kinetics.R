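#' Sampled scalar time series
#'
#' @param times Strictly increasing sample times.
#' @param values Finite values, one per time point.
#' @param unit Time unit, one of `"h"`, `"min"`, `"s"`.
#' @param label Free-text description of the quantity.
#' @return A `time_series` data frame with columns `time` and `value` and
#'   attributes `unit` and `label`.
#' @export
time_series <- function(times, values, unit = c("h", "min", "s"), label = "") {
  unit <- match.arg(unit)
  stopifnot(length(times) == length(values))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("values must be finite")
  structure(data.frame(time = times, value = values),
            unit = unit, label = label,
            class = c("time_series", "data.frame"))
}

#' Degradation rate from log-linear decay
#'
#' Converts the series to natural logarithms and reports minus the ordinary
#' least-squares slope of `ln(value)` against time over the fit window, i.e.
#' the first-order decay rate in reciprocal time units. The estimator is
#' exact on noiseless exponentials and invariant to scaling the series by a
#' positive constant.
#'
#' Values at or below `log_floor` are excluded before taking logs (their
#' count is logged). The default window starts at the first point that has
#' dropped below 95% of the series maximum (the end of any initial plateau)
#' and ends at the last point above the floor; `window` overrides it.
#'
#' @param series A [time_series()] (white-puncta fraction or percentage; the
#'   slope is invariant to that scale choice).
#' @param window Optional integer `c(first, last)` index pair.
#' @param log_floor Values <= this are excluded; default `1e-3 * max(value)`.
#' @return A `rate_estimate` list: `rate` (>= 0 under decay), `window`,
#'   `n_used`, `r_squared`.
#' @export
degradation_rate <- function(series, window = NULL, log_floor = NULL) {
  stopifnot(inherits(series, "time_series"))
  v <- series$value; t <- series$time
  if (is.null(log_floor)) log_floor <- 1e-3 * max(v)
  if (is.null(window)) {
    start <- which(v < 0.95 * max(v))[1]
    if (is.na(start)) start <- 1L
    last_ok <- which(v > log_floor)
    if (length(last_ok) == 0) stop("no values above the log floor")
    window <- c(start, max(last_ok))
  }
  stopifnot(length(window) == 2, window[1] >= 1, window[2] <= length(v),
            window[2] > window[1])
  idx <- seq(window[1], window[2])
  usable <- idx[v[idx] > log_floor]
  if (length(usable) < length(idx))
    log_filter("degradation_rate", length(idx), length(usable), "points")
  if (length(usable) < 3)
    stop("fewer than 3 usable points above the log floor in the fit window")
  if (any(v[usable] <= 0))
    stop("non-positive values survive the log floor; raise log_floor")
  fit <- stats::lm(log(v[usable]) ~ t[usable])
  structure(list(rate = -unname(stats::coef(fit)[2]),
                 window = as.integer(window),
                 n_used = length(usable),
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("degradation rate: %.4g (window %d..%d, n = %d, R^2 = %.3f)\n",
              x$rate, x$window[1], x$window[2], x$n_used, x$r_squared))
  invisible(x)
}

#' Area under the curve of a time series
#'
#' Trapezoidal integral over the observed time range, in value x time units.
#' Additive over adjacent time intervals.
#'
#' @param series A [time_series()] with at least 2 points.
#' @return Scalar AUC.
#' @export
auc <- function(series) {
  stopifnot(inherits(series, "time_series"))
  if (nrow(series) < 2) stop("AUC needs at least 2 points")
  pracma::trapz(series$time, series$value)
}

#' Normalize a FRAP trace to its pre-bleach intensity
#'
#' Divides every intensity by the mean of the first `n_prebleach` frames, so
#' pre-bleach values average 1 and the post-bleach plateau reads directly as
#' the recovered fraction of the initial signal. Scale-invariant: multiplying
#' the whole trace by a positive constant leaves the result unchanged.
#'
#' @param trace A [time_series()] of raw intensities.
#' @param n_prebleach Number of frames acquired before the bleach
#'   (>= 1, < series length).
#' @return Normalized [time_series()].
#' @export
frap_normalize <- function(trace, n_prebleach = 2L) {
  stopifnot(inherits(trace, "time_series"),
            n_prebleach >= 1, n_prebleach < nrow(trace))
  pre <- mean(trace$value[seq_len(n_prebleach)])
  if (pre <= 0) stop("pre-bleach mean intensity is not positive")
  time_series(trace$time, trace$value / pre, unit = attr(trace, "unit"),
              label = paste0(attr(trace, "label"), " (pre-bleach normalized)"))
}

#' Puncta count per frame as a time series
#'
#' @param puncta_sets List of [detect_puncta()] results ordered by frame.
#' @param calibration A [pixel_calibration()] supplying the frame interval
#'   and time unit.
#' @return A [time_series()] of non-negative integer counts.
#' @export
puncta_count_timeseries <- function(puncta_sets, calibration) {
  stopifnot(is.list(puncta_sets), inherits(calibration, "pixel_calibration"))
  counts <- vapply(puncta_sets, nrow, integer(1))
  times <- (seq_along(puncta_sets) - 1) * calibration$frame_interval
  time_series(times, counts, unit = calibration$time_unit,
              label = "puncta count")
}
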