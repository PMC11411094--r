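# Shared fixtures: small specs and series built in code.

# Degenerate, essentially constant composite: no rise, no cycle, no noise,
# vanishing decline. Used wherever a flat series is needed.
flat_spec <- function(baseline = 600, duration = 24, ...) {
  synthetic_spec(baseline_rr = baseline, rise_amplitude = 0,
                 daily_amplitude = 0, noise_sd = 0, beat_jitter_sd = 0,
                 artifact_fraction = 0, decline_rate = 1e-9,
                 turning_offset = duration / 2, duration = duration,
                 calving_time = duration, ...)
}

# Default-condition spec with a per-test seed.
default_spec <- function(seed = 1L, ...) synthetic_spec(seed = seed, ...)

# Short noiseless recording for calibration checks.
noiseless_spec <- function(duration = 24, seed = 1L) {
  synthetic_spec(noise_sd = 0, beat_jitter_sd = 0, artifact_fraction = 0,
                 duration = duration, calving_time = duration,
                 turning_offset = duration / 2, rise_duration = duration / 3,
                 seed = seed)
}

# Decomposition of one default synthetic composite (cached per session).
default_decomposition <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      sp <- synthetic_spec(seed = seed)
      b <- composite_series(generate_components(sp),
                            calving_time = sp$calving_time)
      cache[[key]] <- stl_decompose(b)
    }
    cache[[key]]
  }
})

# The published six-cow remaining-hours table.
study_matrix <- function() calving_study_hours()

# Half-up decimal rounding, the convention of the printed tables
# (base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}
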