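test_that("invalid specifications are rejected with the violated invariant named", {
  expect_error(synthetic_spec(ar_coef = 1.2), "ar_coef")
  expect_error(synthetic_spec(artifact_fraction = 1), "artifact_fraction")
  expect_error(synthetic_spec(decline_rate = 0), "decline_rate")
  expect_error(synthetic_spec(turning_offset = 200, duration = 168),
               "turning_offset")
  expect_error(synthetic_spec(calving_time = 100, duration = 168),
               "calving_time")
  expect_error(synthetic_spec(dropout_segments = list(c(20, 10))),
               "dropout")
})

test_that("degenerate spec yields an essentially constant composite at baseline", {
  sp <- flat_spec(baseline = 600)
  comp <- generate_components(sp)
  expect_true(all(abs(comp$trend_ms - 600) < 1e-6))
  expect_true(all(comp$seasonal_ms == 0))
  expect_true(all(comp$remainder_ms == 0))
})

test_that("identical specs give bit-identical components and beats", {
  sp <- default_spec(seed = 7, duration = 48, calving_time = 48,
                     turning_offset = 20, rise_duration = 12)
  expect_identical(generate_components(sp), generate_components(sp))
  expect_identical(generate_beats(sp), generate_beats(sp))
})

test_that("remainder matches the specified AR(1) moments at large n", {
  sp <- synthetic_spec(duration = 5000, calving_time = 5000,
                       turning_offset = 55, ar_coef = 0.5, noise_sd = 10,
                       seed = 4)
  r <- generate_components(sp)$remainder_ms
  expect_length(r, 10000L)
  ac1 <- stats::cor(r[-1], r[-length(r)])
  expect_lt(abs(ac1 - 0.5), 0.05)
  expect_lt(abs(stats::sd(r) - 10) / 10, 0.05)
})

test_that("clean constant composite gives exactly periodic beats", {
  sp <- flat_spec(baseline = 600, duration = 1)
  beats <- generate_beats(sp)
  expect_true(all(abs(beats$rr_ms - 600) < 1e-6))
  expect_true(all(abs(diff(beats$time_s) - 0.6) < 1e-9))
  expect_equal(beats$time_s[1], 0)
})

test_that("dropout segments delete every beat inside them", {
  sp <- flat_spec(duration = 24, dropout_segments = list(c(10, 20)))
  beats <- generate_beats(sp)
  t_h <- beats$time_s / 3600
  expect_false(any(t_h >= 10 & t_h < 20))
  expect_true(any(t_h < 10) && any(t_h >= 20))
})

test_that("artifact labelling matches the requested fraction", {
  sp <- synthetic_spec(artifact_fraction = 0.05, duration = 20,
                       calving_time = 20, turning_offset = 10,
                       rise_duration = 6, seed = 11)
  beats <- generate_beats(sp)
  expect_gt(nrow(beats), 100000)
  expect_lt(abs(mean(beats$artifact) - 0.05), 0.005)
})

test_that("ground truth reports the turning time or its absence", {
  sp <- synthetic_spec(calving_time = 150, duration = 150,
                       turning_offset = 50)
  rec <- generate_record(flat_spec())
  expect_equal(ground_truth(rec)$calving_time, 24)
  expect_equal(sp$calving_time - sp$turning_offset, 100)
  rec2 <- generate_record(spec_monotone_decline(duration = 24, seed = 2))
  expect_true(is.na(ground_truth(rec2)$true_turning_time))
  # rise_decline truth is calving - offset
  sp3 <- synthetic_spec(duration = 48, calving_time = 48,
                        turning_offset = 20, rise_duration = 12, seed = 3)
  rec3 <- generate_record(sp3)
  expect_equal(ground_truth(rec3)$true_turning_time, 28)
})

test_that("turning offsets drawn from a range imply truths with offsets in that range", {
  offs <- with_rng_seed(5, stats::runif(20, 40, 76))
  truths <- vapply(offs, function(o) {
    sp <- synthetic_spec(turning_offset = o)
    sp$calving_time - sp$turning_offset
  }, numeric(1))
  recovered <- 168 - truths
  expect_true(all(recovered >= 40 & recovered <= 76))
  expect_equal(recovered, offs)
})

test_that("binning noiseless beats recovers the composite within 0.5 ms per bin", {
  sp <- noiseless_spec(duration = 24)
  rec <- generate_record(sp)
  composite <- rec$components$trend_ms + rec$components$seasonal_ms +
    rec$components$remainder_ms
  binned <- bin_series(beat_series(rec$beats$time_s, rec$beats$rr_ms),
                       n_bins = length(composite))
  expect_false(anyNA(binned$rr_ms))
  expect_lt(max(abs(binned$rr_ms - composite)), 0.5)
})
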