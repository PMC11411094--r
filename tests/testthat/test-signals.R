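tri_series <- function(peak_at = 40, n = 80, name = "SMA") {
  v <- -abs(seq_len(n) - peak_at) + 50
  indicator_series(name, (seq_len(n) - 1) * 0.5, v)
}

test_that("retrospective detection is the earliest-tie global argmax", {
  s <- detect_peak_retrospective(tri_series(peak_at = 40))
  expect_true(s$found)
  expect_equal(s$signal_time, 39 * 0.5)
  expect_equal(s$peak_value, 50)

  # plateau of equal maxima: earliest bin wins
  v <- c(1:30, rep(30, 3), 29:1)
  plat <- indicator_series("SMA", (seq_along(v) - 1) * 0.5, v)
  expect_equal(detect_peak_retrospective(plat)$signal_time, 29 * 0.5)

  # windowed search
  w <- detect_peak_retrospective(tri_series(40), window = c(0, 10))
  expect_equal(w$signal_time, 10)

  expect_error(
    detect_peak_retrospective(indicator_series("SMA", 1:3, rep(NA_real_, 3))),
    "no defined")
})

test_that("detection floors declare no signal for flat-low indicators", {
  rsi0 <- indicator_series("RSI", (1:60 - 1) * 0.5, rep(0, 60))
  expect_false(detect_peak_retrospective(rsi0)$found)

  mad_neg <- indicator_series("MAD", (1:60 - 1) * 0.5,
                              -1 + 0.5 * sin(seq_len(60) / 5))
  expect_false(detect_peak_retrospective(mad_neg)$found)
  # the floor is explicit: disabling it reports the (negative) peak
  s <- detect_peak_retrospective(mad_neg, floor = -Inf)
  expect_true(s$found)
  expect_lt(s$peak_value, 0)
})

test_that("online detection confirms a clean peak k bins later, else no signal", {
  tri <- tri_series(peak_at = 40, name = "SMA")
  on <- detect_peak_online(tri, k = 3)
  retro <- detect_peak_retrospective(tri)
  expect_true(on$found)
  expect_equal(on$signal_time, retro$signal_time)
  expect_equal(on$confirmation_lag, 3L)

  low <- indicator_series("MAD", (1:50 - 1) * 0.5, -abs(seq_len(50) - 25))
  expect_false(detect_peak_online(low)$found)  # never exceeds threshold 0
})

test_that("online signals never come later in value than the retrospective peak", {
  for (seed in c(101, 102, 103, 104, 105)) {
    d <- default_decomposition(seed)
    mad <- ind_mad(d)
    on <- detect_peak_online(mad)
    re <- detect_peak_retrospective(mad)
    if (on$found && re$found) {
      expect_lte(on$signal_time, re$signal_time)
    }
  }
})

test_that("combined MAD+RSI signal is gated by both conditions", {
  t <- (1:60 - 1) * 0.5
  mad_pos <- indicator_series("MAD", t, 1 + sin(seq_len(60) / 8))
  rsi_low <- indicator_series("RSI", t, rep(40, 60))
  expect_false(combined_mad_rsi_signal(mad_pos, rsi_low)$found)

  # both conditions hold only in one window containing MAD's max
  v <- c(rep(-1, 10), seq(0.5, 5, length.out = 10),
         seq(4.5, 0.5, length.out = 10), rep(-1, 30))
  mad2 <- indicator_series("MAD", t, v)
  rsi_hi <- indicator_series("RSI", t, ifelse(v > 0, 80, 20))
  cmb <- combined_mad_rsi_signal(mad2, rsi_hi)
  only <- detect_peak_online(mad2)
  expect_true(cmb$found)
  expect_equal(cmb$signal_time, only$signal_time)

  expect_error(
    combined_mad_rsi_signal(mad_pos,
                            indicator_series("RSI", t + 0.25, rep(60, 60))),
    "different grids")
})

test_that("combined signal cannot precede the MAD-only online signal", {
  for (seed in c(111, 112, 113)) {
    d <- default_decomposition(seed)
    mad <- ind_mad(d)
    rsi <- ind_rsi(d)
    cmb <- combined_mad_rsi_signal(mad, rsi)
    only <- detect_peak_online(mad)
    if (cmb$found && only$found) {
      expect_gte(cmb$signal_time, only$signal_time)
    }
  }
})

test_that("remaining hours is calving minus signal, on the half-hour grid", {
  sig <- turning_point("MAD", TRUE, signal_time = 47.5, peak_value = 1,
                       mode = "retrospective")
  expect_equal(remaining_hours(sig, 100)$hours, 52.5)
  expect_equal(remaining_hours(sig, 47.5)$hours, 0)
  expect_error(remaining_hours(sig, 40), "precedes")

  none <- turning_point("RSI", FALSE)
  r <- remaining_hours(none, 100)
  expect_false(r$found)
  expect_true(is.na(r$hours))

  # on the default pipeline the result is a multiple of the bin width
  d <- default_decomposition(101)
  s <- detect_peak_retrospective(ind_mad(d))
  rem <- remaining_hours(s, 168)$hours
  expect_equal(rem %% 0.5, 0)
})

test_that("monotone-decline recordings silence RSI and threshold-gated detectors", {
  sp <- spec_monotone_decline(seed = 17)
  b <- composite_series(generate_components(sp),
                        calving_time = sp$calving_time)
  d <- stl_decompose(b)
  expect_false(detect_peak_retrospective(ind_rsi(d))$found)
  expect_false(detect_peak_online(ind_mad(d))$found)
  expect_false(detect_peak_online(ind_macd(d))$found)
})
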