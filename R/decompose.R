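#' Seasonal-trend decomposition of a binned R-R series
#'
#' Splits the series into trend + daily seasonal + remainder with STL
#' (seasonal-trend decomposition using LOESS). The three components
#' reconstruct the input exactly at every bin. With the default 30-min
#' bins, `period = 48` makes the seasonal component the 24-h daily cycle.
#'
#' The canonical STL settings are used: seasonal window `"periodic"`,
#' trend window chosen by the standard STL formula unless given, trend
#' LOESS degree 1, inner/outer loops 2/0 (Gaussian error model) unless
#' `robust = TRUE`.
#'
#' @param binned A [binned_series()] without missing values (run
#'   [impute_gaps()] first), or a numeric vector.
#' @param period Bins per seasonal cycle (default 48).
#' @param s_window `"periodic"` or an odd integer seasonal LOESS window.
#' @param t_window Odd integer trend LOESS window, or `NULL` for the
#'   standard STL default.
#' @param robust Use robust (iterated) fitting instead of the Gaussian
#'   error model.
#' @return An object of class `rr_decomposition`: list with `time`,
#'   `observed`, `trend`, `seasonal`, `remainder`, `period`,
#'   `method_params`.
#' @export
stl_decompose <- function(binned, period = 48L, s_window = "periodic",
                          t_window = NULL, robust = FALSE) {
  v <- if (inherits(binned, "binned_series")) binned$rr_ms else as.numeric(binned)
  time <- if (inherits(binned, "binned_series")) {
    binned$bin_start_h
  } else {
    (seq_along(v) - 1L) * 0.5
  }
  if (anyNA(v)) {
    stop("series contains missing values; run impute_gaps() first",
         call. = FALSE)
  }
  if (length(v) <= 2L * period) {
    stop(sprintf("series too short for decomposition: %d bins, need more than 2 periods (%d bins)",
                 length(v), 2L * period), call. = FALSE)
  }
  x <- stats::ts(v, frequency = period)
  fit <- if (is.null(t_window)) {
    stats::stl(x, s.window = s_window, robust = robust)
  } else {
    stats::stl(x, s.window = s_window, t.window = t_window, robust = robust)
  }
  comp <- fit$time.series
  structure(list(
    time = time,
    observed = v,
    trend = as.numeric(comp[, "trend"]),
    seasonal = as.numeric(comp[, "seasonal"]),
    remainder = as.numeric(comp[, "remainder"]),
    period = as.integer(period),
    method_params = list(method = "stl", s_window = s_window,
                         t_window = t_window, robust = robust),
    calving_time = if (inherits(binned, "binned_series")) {
      attr(binned, "calving_time")
    } else NULL
  ), class = "rr_decomposition")
}

#' LOESS trend of a binned series
#'
#' Locally weighted polynomial regression of the values on time with
#' tricube weights, mirroring a plain LOESS trend extraction
#' (span 0.75, degree 2, Gaussian errors by default) as an alternative to
#' the STL trend.
#'
#' @param binned A [binned_series()] without missing values, or a numeric
#'   vector.
#' @param span Fraction of points in each local fit, in (0, 1].
#' @param degree Local polynomial degree: 0, 1, or 2.
#' @param family `"gaussian"` (least squares) or `"symmetric"` (robust).
#' @return Numeric vector of fitted trend values on the input grid.
#' @export
loess_trend <- function(binned, span = 0.75, degree = 2,
                        family = c("gaussian", "symmetric")) {
  family <- match.arg(family)
  v <- if (inherits(binned, "binned_series")) binned$rr_ms else as.numeric(binned)
  if (anyNA(v)) {
    stop("series contains missing values; run impute_gaps() first",
         call. = FALSE)
  }
  if (!(span > 0 && span <= 1)) {
    stop("span must be in (0, 1]", call. = FALSE)
  }
  if (!degree %in% 0:2) stop("degree must be 0, 1, or 2", call. = FALSE)
  t <- seq_along(v)
  fit <- stats::loess(v ~ t, span = span, degree = degree, family = family,
                      surface = "direct")
  as.numeric(stats::fitted(fit))
}
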