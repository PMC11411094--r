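#' Specification of a synthetic pre-calving R-R recording
#'
#' Defines all parameters of the phenomenological R-R generator: a baseline
#' R-R level with a smooth pre-calving rise, a sharp linear decline starting
#' at the turning point, a 24-h sinusoidal daily cycle, AR(1) remainder
#' noise on the 30-min grid, and beat-level jitter, multiplicative artifacts
#' and dropout segments. The same specification drives both the component
#' ("truth") series and the beat-level series, so every generated recording
#' carries its own ground truth.
#'
#' Defaults emulate the scale of pre-calving Holter recordings in dairy
#' cows: baseline 650 ms, a 30 ms rise over 48 h peaking 55 h before
#' calving, then a 2 ms/h decline until calving at the end of a 168-h
#' (7-day) recording; 15 ms daily cycle; AR(1) remainder with marginal
#' sd 8 ms and lag-1 correlation 0.6.
#'
#' @param baseline_rr Baseline R-R level (ms).
#' @param rise_amplitude Height of the pre-peak rise (ms, >= 0).
#' @param rise_duration Duration of the rise (h).
#' @param decline_rate Post-peak decline slope (ms per hour, > 0).
#' @param turning_offset Hours before calving at which the trend peaks.
#' @param duration Length of the recording (h).
#' @param calving_time Calving time (h from recording start); must be
#'   `>= duration` (calving at or after the end of the recording).
#' @param daily_amplitude Amplitude of the 24-h cycle (ms).
#' @param daily_phase Phase of the 24-h cycle (radians).
#' @param noise_sd Marginal standard deviation of the AR(1) remainder (ms).
#' @param ar_coef Lag-1 autoregressive coefficient, in (-1, 1).
#' @param beat_jitter_sd Beat-to-beat Gaussian jitter sd (ms).
#' @param artifact_fraction Proportion of beats corrupted by a
#'   multiplicative artifact, in `[0, 1)`.
#' @param artifact_scale_range Two multiplicative factors (> 1); each
#'   artifact multiplies the R-R value by a factor drawn uniformly from this
#'   range, or by its reciprocal (coin flip), emulating missed/spurious
#'   R-wave detections that the 30% exclusion rule should catch.
#' @param dropout_segments List of `c(start_h, end_h)` pairs; beats whose
#'   time falls in a segment are deleted (device-trouble regime).
#' @param mode `"rise_decline"` (default) or `"monotone_decline"` (the
#'   regime in which the trend only falls and RSI never signals).
#' @param rise_shape `"convex"` (default): quarter-cosine rise whose slope
#'   grows to its maximum at the peak, giving the convex run-up into a sharp
#'   corner that makes the indicator peak coincide with the trend peak;
#'   `"s_curve"`: half-cosine ramp with zero slope at both ends.
#' @param bin_width Grid step for the truth components (h).
#' @param seed Integer seed; identical specs give bit-identical output.
#'
#' @return An object of class `synthetic_spec` (a validated list).
#' @seealso [generate_components()], [generate_record()], [generate_beats()]
#' @export
synthetic_spec <- function(baseline_rr = 650,
                           rise_amplitude = 30,
                           rise_duration = 48,
                           decline_rate = 2,
                           turning_offset = 55,
                           duration = 168,
                           calving_time = duration,
                           daily_amplitude = 15,
                           daily_phase = 0,
                           noise_sd = 8,
                           ar_coef = 0.6,
                           beat_jitter_sd = 5,
                           artifact_fraction = 0.02,
                           artifact_scale_range = c(1.4, 2.0),
                           dropout_segments = list(),
                           mode = c("rise_decline", "monotone_decline"),
                           rise_shape = c("convex", "s_curve"),
                           bin_width = 0.5,
                           seed = 1L) {
  mode <- match.arg(mode)
  rise_shape <- match.arg(rise_shape)
  spec <- structure(list(
    baseline_rr = baseline_rr, rise_amplitude = rise_amplitude,
    rise_duration = rise_duration, decline_rate = decline_rate,
    turning_offset = turning_offset, duration = duration,
    calving_time = calving_time, daily_amplitude = daily_amplitude,
    daily_phase = daily_phase, noise_sd = noise_sd, ar_coef = ar_coef,
    beat_jitter_sd = beat_jitter_sd, artifact_fraction = artifact_fraction,
    artifact_scale_range = artifact_scale_range,
    dropout_segments = dropout_segments, mode = mode,
    rise_shape = rise_shape, bin_width = bin_width,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

#' Validate a synthetic recording specification
#'
#' @param spec A `synthetic_spec`.
#' @return `spec`, invisibly; stops with a message naming the violated
#'   invariant otherwise.
#' @export
validate_synthetic_spec <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("`spec` must be created by synthetic_spec()", call. = FALSE)
  }
  for (f in c("baseline_rr", "rise_amplitude", "rise_duration",
              "decline_rate", "turning_offset", "duration", "calving_time",
              "daily_amplitude", "noise_sd", "beat_jitter_sd",
              "artifact_fraction", "bin_width")) {
    if (!is_scalar_num(spec[[f]])) {
      stop_invalid("numeric scalar fields", paste0(f, " is not a finite number"))
    }
  }
  if (spec$baseline_rr <= 0) stop_invalid("baseline_rr > 0", spec$baseline_rr)
  if (spec$rise_amplitude < 0) {
    stop_invalid("rise_amplitude >= 0", spec$rise_amplitude)
  }
  if (spec$decline_rate <= 0) stop_invalid("decline_rate > 0", spec$decline_rate)
  if (spec$daily_amplitude < 0 || spec$noise_sd < 0 || spec$beat_jitter_sd < 0) {
    stop_invalid("amplitude/sd fields non-negative",
                 "daily_amplitude, noise_sd and beat_jitter_sd must be >= 0")
  }
  if (abs(spec$ar_coef) >= 1) stop_invalid("|ar_coef| < 1", spec$ar_coef)
  if (spec$artifact_fraction < 0 || spec$artifact_fraction >= 1) {
    stop_invalid("artifact_fraction in [0, 1)", spec$artifact_fraction)
  }
  if (length(spec$artifact_scale_range) != 2L ||
      any(spec$artifact_scale_range <= 1)) {
    stop_invalid("artifact_scale_range a pair of factors > 1",
                 paste(spec$artifact_scale_range, collapse = ", "))
  }
  if (spec$duration <= 0) stop_invalid("duration > 0", spec$duration)
  if (spec$bin_width <= 0 ||
      abs(spec$duration / spec$bin_width -
          round(spec$duration / spec$bin_width)) > 1e-8) {
    stop_invalid("duration a whole number of bins", spec$bin_width)
  }
  if (spec$mode == "rise_decline") {
    if (!(spec$turning_offset > 0 && spec$turning_offset < spec$duration &&
          spec$duration <= spec$calving_time)) {
      stop_invalid("0 < turning_offset < duration <= calving_time",
                   sprintf("turning_offset=%g, duration=%g, calving_time=%g",
                           spec$turning_offset, spec$duration,
                           spec$calving_time))
    }
    if (spec$rise_duration <= 0) {
      stop_invalid("rise_duration > 0", spec$rise_duration)
    }
  }
  for (seg in spec$dropout_segments) {
    if (length(seg) != 2L || seg[1] >= seg[2]) {
      stop_invalid("dropout segments are (start, end) with start < end",
                   paste(seg, collapse = ", "))
    }
  }
  invisible(spec)
}

# The noiseless trend as a function of time (hours).
trend_function <- function(spec) {
  if (spec$mode == "monotone_decline") {
    return(function(t) spec$baseline_rr - spec$decline_rate * t)
  }
  t_turn <- spec$calving_time - spec$turning_offset
  t0 <- t_turn - spec$rise_duration
  peak <- spec$baseline_rr + spec$rise_amplitude
  shape <- spec$rise_shape
  A <- spec$rise_amplitude
  D <- spec$rise_duration
  function(t) {
    out <- numeric(length(t))
    pre <- t < t0
    rise <- t >= t0 & t <= t_turn
    post <- t > t_turn
    out[pre] <- spec$baseline_rr
    tau <- (t[rise] - t0) / D
    out[rise] <- if (shape == "convex") {
      spec$baseline_rr + A * (1 - cos(pi * tau / 2))
    } else {
      spec$baseline_rr + A * (1 - cos(pi * tau)) / 2
    }
    out[post] <- peak - spec$decline_rate * (t[post] - t_turn)
    out
  }
}

# Components evaluated at bin centres; remainder drawn from the current RNG
# stream (callers wrap in with_rng_seed()).
components_core <- function(spec) {
  n <- as.integer(round(spec$duration / spec$bin_width))
  bin_start <- (seq_len(n) - 1L) * spec$bin_width
  centre <- bin_start + spec$bin_width / 2
  trend <- trend_function(spec)(centre)
  seasonal <- spec$daily_amplitude *
    sin(2 * pi * centre / 24 + spec$daily_phase)
  if (spec$noise_sd > 0) {
    innov_sd <- spec$noise_sd * sqrt(1 - spec$ar_coef^2)
    x0 <- stats::rnorm(1L, 0, spec$noise_sd)
    e <- stats::rnorm(n, 0, innov_sd)
    remainder <- as.numeric(
      stats::filter(e, spec$ar_coef, method = "recursive", init = x0))
  } else {
    remainder <- numeric(n)
  }
  list(bin_start_h = bin_start, trend = trend, seasonal = seasonal,
       remainder = remainder)
}

#' Generate the ground-truth trend, daily cycle, and remainder
#'
#' Evaluates the specified components on the 30-min grid (at bin centres,
#' labelled by bin start). The remainder is a stationary AR(1) Gaussian
#' sequence with marginal sd `noise_sd` and lag-1 correlation `ar_coef`.
#' Trend + seasonal + remainder is the composite the beat generator samples.
#'
#' @param spec A [synthetic_spec()].
#' @return A data frame with columns `bin_start_h`, `trend_ms`,
#'   `seasonal_ms`, `remainder_ms`.
#' @export
generate_components <- function(spec) {
  validate_synthetic_spec(spec)
  comp <- with_rng_seed(spec$seed, components_core(spec))
  data.frame(bin_start_h = comp$bin_start_h, trend_ms = comp$trend,
             seasonal_ms = comp$seasonal, remainder_ms = comp$remainder)
}

# Beat-level generation from a per-bin composite. Within a bin the composite
# is taken constant (its bin value), so bin means of clean beats recover the
# composite exactly. Successive beat times advance by the instantaneous R-R.
beats_core <- function(spec, composite) {
  n_bins <- length(composite)
  bw_s <- spec$bin_width * 3600
  jit <- spec$beat_jitter_sd
  t_cur <- 0
  times <- vector("list", n_bins)
  rrs <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    end_s <- b * bw_s
    c_b <- composite[b]
    if (c_b <= 0) {
      stop("composite R-R is non-positive in bin ", b, call. = FALSE)
    }
    bt <- numeric(0)
    brr <- numeric(0)
    while (t_cur < end_s) {
      step_floor <- max(c_b - 6 * jit, c_b * 0.2, 50) / 1000
      m <- as.integer(ceiling((end_s - t_cur) / step_floor)) + 8L
      rr <- c_b + if (jit > 0) stats::rnorm(m, 0, jit) else numeric(m)
      rr <- pmax(rr, 50)  # physiological floor, keeps times increasing
      tt <- t_cur + c(0, cumsum(rr[-m])) / 1000
      keep <- tt < end_s
      bt <- c(bt, tt[keep])
      brr <- c(brr, rr[keep])
      k <- sum(keep)
      t_cur <- if (k > 0) bt[k] + brr[k] / 1000 else t_cur + rr[1] / 1000
      if (k == m) next  # chunk exhausted before reaching bin end
    }
    times[[b]] <- bt
    rrs[[b]] <- brr
  }
  time_s <- unlist(times, use.names = FALSE)
  rr_true <- unlist(rrs, use.names = FALSE)
  n <- length(time_s)

  artifact <- rep(FALSE, n)
  rr_obs <- rr_true
  if (spec$artifact_fraction > 0 && n > 0) {
    artifact <- stats::runif(n) < spec$artifact_fraction
    n_art <- sum(artifact)
    if (n_art > 0) {
      f <- stats::runif(n_art, spec$artifact_scale_range[1],
                        spec$artifact_scale_range[2])
      inv <- stats::runif(n_art) < 0.5
      f[inv] <- 1 / f[inv]
      rr_obs[artifact] <- rr_true[artifact] * f
    }
  }
  keep <- rep(TRUE, n)
  for (seg in spec$dropout_segments) {
    keep <- keep & !(time_s / 3600 >= seg[1] & time_s / 3600 < seg[2])
  }
  data.frame(time_s = time_s[keep], rr_ms = rr_obs[keep],
             artifact = artifact[keep])
}

#' Generate a complete synthetic recording with ground truth
#'
#' Runs the component and beat generators under the spec's seed and returns
#' the beats together with the truth needed to score detection: the
#' component series, the true turning time (absent in monotone-decline
#' mode) and the calving time.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `rr_record`: a list with elements `beats`
#'   (a [beat_series()] data frame with an `artifact` flag column),
#'   `components` (as [generate_components()]), `true_turning_time` (hours,
#'   `NA` in monotone-decline mode), `calving_time`, and `spec`.
#' @export
generate_record <- function(spec) {
  validate_synthetic_spec(spec)
  out <- with_rng_seed(spec$seed, {
    comp <- components_core(spec)
    composite <- comp$trend + comp$seasonal + comp$remainder
    beats <- beats_core(spec, composite)
    list(comp = comp, beats = beats)
  })
  comp_df <- data.frame(bin_start_h = out$comp$bin_start_h,
                        trend_ms = out$comp$trend,
                        seasonal_ms = out$comp$seasonal,
                        remainder_ms = out$comp$remainder)
  structure(list(
    beats = out$beats,
    components = comp_df,
    true_turning_time = if (spec$mode == "rise_decline") {
      spec$calving_time - spec$turning_offset
    } else NA_real_,
    calving_time = spec$calving_time,
    spec = spec
  ), class = "rr_record")
}

#' Generate only the beat-level series
#'
#' @param spec A [synthetic_spec()].
#' @return A data frame `time_s`, `rr_ms`, `artifact`.
#' @export
generate_beats <- function(spec) {
  generate_record(spec)$beats
}

#' Ground truth of a synthetic recording
#'
#' @param record An `rr_record`.
#' @return A list with `true_turning_time` (hours from start; `NA` when the
#'   trend declines monotonically and no turning point exists) and
#'   `calving_time` (hours from start).
#' @export
ground_truth <- function(record) {
  stopifnot(inherits(record, "rr_record"))
  list(true_turning_time = record$true_turning_time,
       calving_time = record$calving_time)
}

#' Noise-free composite of a record as a binned series
#'
#' Sums the true components into the 30-min composite, the series the
#' analysis stages consume when the beat level is not needed.
#'
#' @param record An `rr_record`, or a components data frame from
#'   [generate_components()].
#' @param calving_time Optional calving time to attach (taken from the
#'   record when available).
#' @return A [binned_series()].
#' @export
composite_series <- function(record, calving_time = NULL) {
  comp <- if (inherits(record, "rr_record")) record$components else record
  if (is.null(calving_time) && inherits(record, "rr_record")) {
    calving_time <- record$calving_time
  }
  binned_series(comp$bin_start_h,
                comp$trend_ms + comp$seasonal_ms + comp$remainder_ms,
                bin_width = if (length(comp$bin_start_h) > 1) {
                  comp$bin_start_h[2] - comp$bin_start_h[1]
                } else 0.5,
                calving_time = calving_time)
}

#' Preset for a monotone-decline recording
#'
#' Emulates the cow whose R-R trend only fell during monitoring — a cow
#' already in its accelerating pre-calving heart-rate rise when the device
#' was attached. The defining feature of this regime is that the extracted
#' trend declines monotonically, so it never crosses its own moving
#' average from below and RSI sits at 0 throughout, producing no signal;
#' the decline rate (1.2 ms/h over a 5-day recording) is set steep enough
#' relative to the remainder noise that the extracted trend is genuinely
#' monotone, as observed in that cow.
#'
#' @param ... Overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
spec_monotone_decline <- function(...) {
  args <- list(...)
  defaults <- list(mode = "monotone_decline", baseline_rr = 660,
                   decline_rate = 1.2, duration = 120, rise_amplitude = 0)
  defaults[names(args)] <- args
  do.call(synthetic_spec, defaults)
}
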