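#' Turning-point signal container
#'
#' @param indicator Indicator name.
#' @param found Whether a signal was found.
#' @param signal_time Bin-grid time of the detected peak (hours).
#' @param peak_value Indicator value at the peak.
#' @param mode `"retrospective"` or `"online"`.
#' @param confirmation_lag Bins waited to confirm (online only).
#' @return An object of class `turning_point`.
#' @keywords internal
turning_point <- function(indicator, found, signal_time = NA_real_,
                          peak_value = NA_real_,
                          mode = c("retrospective", "online"),
                          confirmation_lag = NA_integer_) {
  mode <- match.arg(mode)
  structure(list(indicator = indicator, found = found,
                 signal_time = if (found) signal_time else NA_real_,
                 peak_value = if (found) peak_value else NA_real_,
                 mode = mode, confirmation_lag = confirmation_lag),
            class = "turning_point")
}

#' @export
#' @method print turning_point
print.turning_point <- function(x, ...) {
  if (x$found) {
    cat(sprintf("<turning_point> %s (%s): t = %g h, peak = %.4g\n",
                x$indicator, x$mode, x$signal_time, x$peak_value))
  } else {
    cat(sprintf("<turning_point> %s (%s): no signal\n", x$indicator, x$mode))
  }
  invisible(x)
}

# Default detection floors: an indicator that never exceeds its floor is
# considered to have produced no signal (the monotone-decline RSI case).
default_floor <- function(name) {
  switch(name, MAD = 0, MACD = 0, RSI = 50, -Inf)
}

#' Retrospective turning-point detection (global peak)
#'
#' The turning point is the time of the global maximum of the indicator's
#' defined values within `window`; ties go to the earliest bin. When the
#' indicator never strictly exceeds its detection floor (MAD/MACD: 0,
#' RSI: 50, SMA: none) the series is considered signal-free and
#' `found = FALSE` is returned — the behaviour of RSI on a monotonically
#' declining trend, which sits at 0 throughout.
#'
#' @param ind An [indicator_series()].
#' @param window Optional `c(lo, hi)` time range (hours) to search.
#' @param floor Detection floor; default chosen from the indicator name.
#'   Use `-Inf` to always report the peak.
#' @return A `turning_point`.
#' @export
detect_peak_retrospective <- function(ind, window = NULL, floor = NULL) {
  stopifnot(inherits(ind, "indicator_series"))
  if (is.null(floor)) floor <- default_floor(ind$name)
  sel <- !is.na(ind$value)
  if (!is.null(window)) {
    sel <- sel & ind$time >= window[1] & ind$time <= window[2]
  }
  if (!any(sel)) {
    stop("no defined indicator values in the detection window", call. = FALSE)
  }
  v <- ind$value[sel]
  t <- ind$time[sel]
  if (!any(v > floor)) {
    return(turning_point(ind$name, found = FALSE, mode = "retrospective"))
  }
  i <- which.max(v)  # earliest bin on exact ties
  turning_point(ind$name, found = TRUE, signal_time = t[i], peak_value = v[i],
                mode = "retrospective")
}

# Scan one contiguous run of defined values for the first confirmed peak.
scan_online_run <- function(v, t, k, threshold) {
  m <- length(v)
  if (m < k + 1L) return(NULL)
  for (j in seq_len(m - k)) {
    if (!(v[j] > threshold)) next
    if (j > 1L && v[j] < v[j - 1L]) next          # not a local max
    seg <- v[j:(j + k)]
    if (all(diff(seg) <= 0)) {
      return(list(j = j, time = t[j], value = v[j]))
    }
  }
  NULL
}

#' Online turning-point detection with confirmation lag
#'
#' Scans forward through the indicator; a candidate local maximum whose
#' value exceeds `threshold` is confirmed as the turning point once `k`
#' consecutive non-increasing bins follow it. The first confirmed
#' candidate wins, so the alert becomes available `k` bins (k x 30 min)
#' after the peak itself. Default thresholds follow the indicators'
#' signalling conventions: MAD > 0, MACD > 0, RSI > 50, SMA unthresholded.
#'
#' @param ind An [indicator_series()].
#' @param k Confirmation lag in bins (default 3 = 1.5 h).
#' @param threshold Candidate floor; default chosen from the indicator
#'   name.
#' @return A `turning_point` with `confirmation_lag = k`;
#'   `found = FALSE` when no candidate is ever confirmed.
#' @export
detect_peak_online <- function(ind, k = 3L, threshold = NULL) {
  stopifnot(inherits(ind, "indicator_series"))
  if (!is_count(k)) stop("k must be a positive count", call. = FALSE)
  k <- as.integer(k)
  if (is.null(threshold)) threshold <- default_floor(ind$name)
  ok <- !is.na(ind$value)
  if (!any(ok)) {
    return(turning_point(ind$name, found = FALSE, mode = "online",
                         confirmation_lag = k))
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    idx <- starts[r]:ends[r]
    hit <- scan_online_run(ind$value[idx], ind$time[idx], k, threshold)
    if (!is.null(hit)) {
      return(turning_point(ind$name, found = TRUE, signal_time = hit$time,
                           peak_value = hit$value, mode = "online",
                           confirmation_lag = k))
    }
  }
  turning_point(ind$name, found = FALSE, mode = "online",
                confirmation_lag = k)
}

#' Combined MAD + RSI signal
#'
#' Online detection restricted to bins where MAD > 0 and RSI > 50 hold
#' simultaneously; the peak is taken on MAD. Combining the trend indicator
#' with the momentum oscillator suppresses candidates outside genuine
#' upward phases.
#'
#' @param mad A MAD [indicator_series()].
#' @param rsi An RSI [indicator_series()] on the same grid.
#' @param k Confirmation lag in bins.
#' @return A `turning_point` with indicator `"MAD+RSI"`.
#' @export
combined_mad_rsi_signal <- function(mad, rsi, k = 3L) {
  stopifnot(inherits(mad, "indicator_series"),
            inherits(rsi, "indicator_series"))
  if (length(mad$time) != length(rsi$time) ||
      any(abs(mad$time - rsi$time) > 1e-8)) {
    stop("MAD and RSI series are on different grids", call. = FALSE)
  }
  keep <- !is.na(mad$value) & !is.na(rsi$value) &
    mad$value > 0 & rsi$value > 50
  masked <- indicator_series("MAD+RSI", mad$time,
                             ifelse(keep, mad$value, NA_real_),
                             params = list(k = k))
  detect_peak_online(masked, k = k, threshold = 0)
}

#' Remaining time from a signal to calving
#'
#' @param signal A `turning_point`.
#' @param calving_time Calving time (hours from recording start).
#' @param subject_id Optional subject label.
#' @return A list of class `remaining_time` with `subject_id`, `indicator`,
#'   `hours` (`NA` when the signal was not found) and `found`.
#' @export
remaining_hours <- function(signal, calving_time, subject_id = NA_character_) {
  stopifnot(inherits(signal, "turning_point"))
  if (!signal$found) {
    return(structure(list(subject_id = subject_id,
                          indicator = signal$indicator,
                          hours = NA_real_, found = FALSE),
                     class = "remaining_time"))
  }
  if (calving_time < signal$signal_time) {
    stop("calving_time precedes the signal time", call. = FALSE)
  }
  structure(list(subject_id = subject_id, indicator = signal$indicator,
                 hours = calving_time - signal$signal_time, found = TRUE),
            class = "remaining_time")
}

#' Flag trend/indicator divergence
#'
#' Over a trailing window, fits the sign of the slope of the underlying
#' trend and of the indicator; bins where the two move in opposite
#' directions are flagged. Divergence is a leading reversal cue in
#' technical analysis; the flag is informational and never gates a signal.
#'
#' @param trend Numeric trend series (or [stl_decompose()] result).
#' @param ind An [indicator_series()] on the same grid.
#' @param window Trailing window in bins (default 12).
#' @return Logical vector, `NA` where either slope is undefined.
#' @export
divergence_flag <- function(trend, ind, window = 12L) {
  tv <- if (inherits(trend, "rr_decomposition")) trend$trend else as.numeric(trend)
  iv <- ind$value
  stopifnot(length(tv) == length(iv))
  n <- length(tv)
  slope <- function(v, i) {
    w <- v[(i - window + 1L):i]
    if (anyNA(w)) return(NA_real_)
    x <- seq_along(w)
    sum((x - mean(x)) * (w - mean(w))) / sum((x - mean(x))^2)
  }
  out <- rep(NA, n)
  if (n >= window) {
    for (i in window:n) {
      st <- slope(tv, i)
      si <- slope(iv, i)
      if (!is.na(st) && !is.na(si)) out[i] <- sign(st) * sign(si) < 0
    }
  }
  out
}
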