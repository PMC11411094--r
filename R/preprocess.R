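#' Beat-level R-R series
#'
#' A data frame of beat timestamps (seconds from recording start, strictly
#' increasing) and R-R intervals (ms, positive).
#'
#' @param time_s Beat times in seconds, strictly increasing.
#' @param rr_ms R-R intervals in milliseconds, positive.
#' @return A data frame of class `beat_series`.
#' @export
beat_series <- function(time_s, rr_ms) {
  time_s <- as.numeric(time_s)
  rr_ms <- as.numeric(rr_ms)
  if (length(time_s) != length(rr_ms)) {
    stop("time_s and rr_ms must have the same length", call. = FALSE)
  }
  if (anyNA(time_s) || anyNA(rr_ms)) {
    stop("beat series may not contain missing values", call. = FALSE)
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    stop("beat times must be strictly increasing", call. = FALSE)
  }
  if (any(rr_ms <= 0)) stop("R-R intervals must be positive", call. = FALSE)
  structure(data.frame(time_s = time_s, rr_ms = rr_ms),
            class = c("beat_series", "data.frame"))
}

#' Regular 30-min (or other) grid of mean R-R values
#'
#' @param bin_start_h Bin start times, hours from recording start, on a
#'   regular grid.
#' @param rr_ms Mean R-R per bin (ms), `NA` for missing bins.
#' @param bin_width Grid step in hours (default 0.5).
#' @param calving_time Optional calving time (hours from start) carried as
#'   an attribute.
#' @return A data frame of class `binned_series`.
#' @export
binned_series <- function(bin_start_h, rr_ms, bin_width = 0.5,
                          calving_time = NULL) {
  bin_start_h <- as.numeric(bin_start_h)
  rr_ms <- as.numeric(rr_ms)
  if (length(bin_start_h) != length(rr_ms)) {
    stop("bin_start_h and rr_ms must have the same length", call. = FALSE)
  }
  if (length(bin_start_h) > 1 &&
      any(abs(diff(bin_start_h) - bin_width) > 1e-8)) {
    stop("bin grid must be regular with step bin_width", call. = FALSE)
  }
  if (any(rr_ms <= 0, na.rm = TRUE)) {
    stop("binned R-R values must be positive where present", call. = FALSE)
  }
  structure(data.frame(bin_start_h = bin_start_h, rr_ms = rr_ms),
            bin_width = bin_width, calving_time = calving_time,
            class = c("binned_series", "data.frame"))
}

#' Remove artifactual beats by the running 30% deviation rule
#'
#' A beat is excluded when its R-R interval deviates from the running
#' average by more than `threshold` (strict inequality; a beat at exactly
#' the threshold is kept). The running average is the mean of the last
#' `window` previously *accepted* beats; until that many beats have been
#' accepted, the mean of all previously accepted beats is used. The first
#' beat is always accepted, and removed beats never enter later means, so
#' the rule is causal and usable online.
#'
#' @param beats A [beat_series()] (extra columns are carried through).
#' @param threshold Maximum tolerated relative deviation (default 0.30).
#' @param window Number of preceding accepted beats in the running mean.
#' @return A list with `beats` (the surviving series) and `removed`
#'   (integer indices of removed beats in the input).
#' @export
filter_outliers <- function(beats, threshold = 0.30, window = 60L) {
  stopifnot(is.data.frame(beats))
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  if (!is_count(window)) stop("window must be a positive count", call. = FALSE)
  n <- nrow(beats)
  if (n == 0L) return(list(beats = beats, removed = integer(0)))
  rr <- beats$rr_ms
  window <- as.integer(window)
  keep <- logical(n)
  buf <- numeric(window)   # ring buffer of last accepted values
  buf_n <- 0L
  buf_pos <- 0L
  buf_sum <- 0
  tot_sum <- 0             # running sum/count of all accepted beats
  tot_n <- 0L
  for (i in seq_len(n)) {
    if (tot_n == 0L) {
      ok <- TRUE
    } else {
      m <- if (buf_n >= window) buf_sum / window else tot_sum / tot_n
      ok <- abs(rr[i] - m) / m <= threshold
    }
    if (ok) {
      keep[i] <- TRUE
      tot_sum <- tot_sum + rr[i]
      tot_n <- tot_n + 1L
      buf_pos <- buf_pos %% window + 1L
      if (buf_n == window) buf_sum <- buf_sum - buf[buf_pos]
      buf[buf_pos] <- rr[i]
      buf_sum <- buf_sum + rr[i]
      if (buf_n < window) buf_n <- buf_n + 1L
    }
  }
  out <- beats[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(beats)
  list(beats = out, removed = which(!keep))
}

#' Average beats onto a regular bin grid
#'
#' Bins are left-closed, right-open intervals aligned to the recording
#' start; a bin's value is the arithmetic mean R-R of the beats whose time
#' falls in it. Bins holding fewer than `min_beats` beats are set missing.
#'
#' @param beats A [beat_series()].
#' @param bin_width Bin width in hours (default 0.5 = 30 min).
#' @param min_beats Minimum beats required to accept a bin (default 30).
#' @param n_bins Number of bins; default covers the last beat.
#' @param calving_time Optional calving time attached to the result.
#' @return A [binned_series()].
#' @export
bin_series <- function(beats, bin_width = 0.5, min_beats = 30L,
                       n_bins = NULL, calving_time = NULL) {
  stopifnot(is.data.frame(beats), bin_width > 0)
  if (nrow(beats) == 0L) {
    return(binned_series(numeric(0), numeric(0), bin_width = bin_width,
                         calving_time = calving_time))
  }
  t_h <- beats$time_s / 3600
  idx <- floor(t_h / bin_width) + 1L
  if (is.null(n_bins)) n_bins <- max(idx)
  in_range <- idx >= 1L & idx <= n_bins
  idx <- idx[in_range]
  counts <- tabulate(idx, nbins = n_bins)
  sums <- numeric(n_bins)
  agg <- rowsum(beats$rr_ms[in_range], idx, reorder = TRUE)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  value <- ifelse(counts >= min_beats, sums / pmax(counts, 1L), NA_real_)
  binned_series((seq_len(n_bins) - 1L) * bin_width, value,
                bin_width = bin_width, calving_time = calving_time)
}

#' Fill interior gaps in a binned series by linear interpolation
#'
#' Leading and trailing missing bins are trimmed off. Interior runs of up
#' to `max_gap` missing bins are filled by linear interpolation between the
#' flanking present values; a longer run is an error (the recording is
#' considered unusable, as for the two device-trouble cows).
#'
#' @param binned A [binned_series()].
#' @param max_gap Longest imputable run of missing bins (default 48 = 24 h).
#' @return A [binned_series()] without missing values, with an `imputed`
#'   attribute giving the (post-trim) indices that were filled.
#' @export
impute_gaps <- function(binned, max_gap = 48L) {
  stopifnot(inherits(binned, "binned_series"))
  v <- binned$rr_ms
  if (!anyNA(v)) {
    attr(binned, "imputed") <- integer(0)
    return(binned)
  }
  present <- which(!is.na(v))
  if (length(present) == 0L) {
    stop("unimputable gap: the series has no present values", call. = FALSE)
  }
  lo <- present[1]
  hi <- present[length(present)]
  v <- v[lo:hi]
  t <- binned$bin_start_h[lo:hi]
  r <- rle(is.na(v))
  if (any(r$values & r$lengths > max_gap)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- which(r$values & r$lengths > max_gap)[1]
    stop(sprintf(
      "unimputable gap: %d consecutive missing bins (bins %g-%g h) exceed max_gap = %d",
      r$lengths[bad], t[starts[bad]], t[ends[bad]], max_gap), call. = FALSE)
  }
  filled <- stats::approx(t[!is.na(v)], v[!is.na(v)], xout = t,
                          method = "linear")$y
  out <- binned_series(t, filled, bin_width = attr(binned, "bin_width"),
                       calving_time = attr(binned, "calving_time"))
  attr(out, "imputed") <- which(is.na(v))
  out
}

#' Convert R-R intervals (ms) to heart rate (bpm) and back
#'
#' HR (bpm) = 60 / R-R (s).
#'
#' @param rr_ms R-R intervals in milliseconds, positive.
#' @return Heart rate in beats per minute.
#' @export
rr_to_hr <- function(rr_ms) {
  if (any(rr_ms <= 0, na.rm = TRUE)) {
    stop("R-R intervals must be positive", call. = FALSE)
  }
  60000 / rr_ms
}

#' @rdname rr_to_hr
#' @param hr_bpm Heart rate in beats per minute, positive.
#' @export
hr_to_rr <- function(hr_bpm) {
  if (any(hr_bpm <= 0, na.rm = TRUE)) {
    stop("heart rate must be positive", call. = FALSE)
  }
  60000 / hr_bpm
}
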