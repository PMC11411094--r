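rand_series <- function(n = 200, seed = 3) {
  with_rng_seed(seed, 650 + cumsum(stats::rnorm(n, 0, 2)))
}

test_that("SMA equals the brute-force windowed mean with an 11-bin warm-up", {
  s <- ind_sma(rep(700, 40), n = 12)
  expect_equal(s$warm_up, 11L)
  expect_true(all(is.na(s$value[1:11])))
  expect_true(all(s$value[12:40] == 700))

  expect_equal(ind_sma(1:12, n = 12)$value[12], 6.5)

  x <- rand_series()
  v <- ind_sma(x, n = 12)$value
  for (t in seq(12, 200, by = 13)) {
    expect_equal(v[t], mean(x[(t - 11):t]), tolerance = 1e-12)
  }
  expect_warning(ind_sma(1:5, n = 12), "exceeds")
})

test_that("EMA follows the alpha = 2/(n+1) recursion from an SMA start", {
  expect_true(all(ind_ema(rep(640, 30), n = 9)$value[9:30] == 640))
  expect_equal(ind_ema(rand_series(50), n = 1)$value, rand_series(50))

  step <- c(rep(0, 20), rep(1, 40))
  e <- ind_ema(step, n = 9)$value
  # independent recursion oracle
  alpha <- 2 / 10
  oracle <- rep(NA_real_, 60)
  oracle[9] <- 0
  for (t in 10:60) oracle[t] <- alpha * step[t] + (1 - alpha) * oracle[t - 1]
  expect_equal(e, oracle, tolerance = 1e-12)

  # bounded by the input range after warm-up
  x <- rand_series(300, seed = 12)
  v <- ind_ema(x, n = 14)$value
  expect_true(all(v[!is.na(v)] >= min(x) & v[!is.na(v)] <= max(x)))
})

test_that("MAD measures deviation from the SMA in percent or ms", {
  expect_true(all(ind_mad(rep(650, 30))$value[12:30] == 0))
  expect_true(all(ind_mad(rep(650, 30), mode = "difference")$value[12:30] == 0))

  x <- c(rep(7693 / 11, 11), 707)  # SMA of the 12 values is exactly 700
  expect_equal(ind_mad(x)$value[12], 1.0, tolerance = 1e-12)
  expect_equal(ind_mad(x, mode = "difference")$value[12], 7.0,
               tolerance = 1e-12)

  # sign flips from + to - as the series crosses its SMA on the way down
  y <- c(seq(600, 660, by = 5), seq(655, 560, by = -5))
  m <- ind_mad(y)$value
  expect_gt(m[14], 0)
  expect_lt(m[length(y)], 0)
})

test_that("MACD is the short/long EMA difference with its documented limits", {
  expect_error(ind_macd(rand_series(), short = 26, long = 12), "short < long")
  expect_true(all(abs(ind_macd(rep(700, 60))$value[26:60]) < 1e-12))

  # linear ramp: difference-mode MACD converges to b * (long - short) / 2
  b <- 2
  ramp <- 100 + b * seq_len(120)
  m <- ind_macd(ramp, short = 5, long = 10, mode = "difference")$value
  expect_lt(abs(m[120] - b * (10 - 5) / 2) / (b * 2.5), 0.01)

  # bin-wise equality with independently computed EMA recursions
  x <- rand_series(150, seed = 21)
  ema_oracle <- function(p, n) {
    a <- 2 / (n + 1)
    e <- rep(NA_real_, length(p))
    e[n] <- mean(p[1:n])
    for (t in (n + 1):length(p)) e[t] <- a * p[t] + (1 - a) * e[t - 1]
    e
  }
  diff_macd <- ind_macd(x, 12, 26, mode = "difference")$value
  expect_equal(diff_macd, ema_oracle(x, 12) - ema_oracle(x, 26),
               tolerance = 1e-12)
})

test_that("RSI hits its 100/0/50 limits and stays within [0, 100]", {
  expect_true(all(ind_rsi(seq(1, 50))$value[15:50] == 100))
  expect_true(all(ind_rsi(seq(50, 1))$value[15:50] == 0))
  alt <- 600 + rep(c(1, 0), 30)
  expect_true(all(ind_rsi(alt)$value[15:60] == 50))
  expect_true(all(ind_rsi(rep(640, 40))$value[15:40] == 50))  # no changes

  x <- rand_series(300, seed = 31)
  r <- ind_rsi(x)$value
  expect_true(all(r[!is.na(r)] >= 0 & r[!is.na(r)] <= 100))
  # negation symmetry when no zero changes occur
  r_neg <- ind_rsi(-x)$value
  expect_equal(r_neg[!is.na(r_neg)], 100 - r[!is.na(r)], tolerance = 1e-9)
})

test_that("percent-mode indicators are scale invariant; moving averages scale", {
  x <- rand_series(200, seed = 41)
  k <- 3.7
  expect_equal(ind_mad(k * x)$value, ind_mad(x)$value, tolerance = 1e-9)
  expect_equal(ind_macd(k * x)$value, ind_macd(x)$value, tolerance = 1e-9)
  expect_equal(ind_rsi(k * x)$value, ind_rsi(x)$value, tolerance = 1e-9)
  expect_equal(ind_sma(k * x)$value, k * ind_sma(x)$value, tolerance = 1e-9)
  expect_equal(ind_ema(k * x)$value, k * ind_ema(x)$value, tolerance = 1e-9)
})

test_that("warm-up regions are exactly as documented", {
  x <- rand_series(60, seed = 51)
  for (ind in list(ind_sma(x, 12), ind_mad(x, 12), ind_macd(x, 12, 26),
                   ind_rsi(x, 14), ind_ema(x, 9))) {
    expect_true(all(is.na(ind$value[seq_len(ind$warm_up)])))
    expect_false(is.na(ind$value[ind$warm_up + 1L]))
  }
})
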