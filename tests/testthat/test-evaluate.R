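test_that("marginal summaries reproduce every printed mean and sd of the study table", {
  s <- summarize_remaining(study_matrix())
  rows <- s$rows
  expect_equal(round_half_up(rows$mean), c(54.1, 58.7, 55.5, 55.7))
  expect_equal(round_half_up(rows$sd), c(11.3, 12.3, 11.4, 11.9))
  expect_equal(rows$n, c(5, 6, 6, 5))

  cols <- s$cols
  expect_equal(round_half_up(cols$mean), c(54.6, 72.4, 62.8, 42.8, 44.3, 53.1))
  expect_equal(round_half_up(cols$sd), c(1.6, 2.7, 2.2, 0.4, 2.2, 9.8))
  expect_equal(round_half_up(cols$sd[4], 2), 0.35)
})

test_that("single-observation marginals have no standard deviation", {
  m <- matrix(c(10, NA, 12, 14), nrow = 2,
              dimnames = list(c("MAD", "MACD"), c("a", "b")))
  s <- summarize_remaining(m)
  expect_true(is.na(s$cols$sd[s$cols$subject_id == "a"]))
  expect_equal(s$cols$mean[s$cols$subject_id == "a"], 10)
})

test_that("coefficient of variation matches hand arithmetic and the study's h886", {
  m <- study_matrix()
  expect_equal(round_half_up(cv_percent(m[, "h886"])), 18.5)
  expect_equal(cv_percent(c(5, 5, 5)), 0)
  expect_equal(round(cv_percent(c(10, 20)), 1), 47.1)
  expect_error(cv_percent(c(3)), "at least two")
  expect_error(cv_percent(c(-5, 1)), "positive")
})

test_that("blocked omnibus F matches a direct sums-of-squares oracle", {
  # synthetic complete matrix with additive subject and indicator effects
  subj_eff <- c(0, 4, -3, 7, 1)
  ind_eff <- c(0, 2, -1)
  noise <- matrix(with_rng_seed(77, stats::rnorm(15, 0, 1)), nrow = 3)
  m <- 50 + outer(ind_eff, subj_eff, `+`) + noise
  dimnames(m) <- list(c("MAD", "MACD", "RSI"), paste0("s", 1:5))

  res <- omnibus_compare(m)

  # oracle: randomized-block ANOVA from first principles
  a <- nrow(m); b <- ncol(m)
  grand <- mean(m)
  ss_ind <- b * sum((rowMeans(m) - grand)^2)
  ss_sub <- a * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_res <- ss_tot - ss_ind - ss_sub
  F_oracle <- (ss_ind / (a - 1)) / (ss_res / ((a - 1) * (b - 1)))
  expect_equal(res$F, F_oracle, tolerance = 1e-8)
  expect_equal(res$df, c(2, 8))

  # permuting subject labels leaves F unchanged
  perm <- m[, c(3, 1, 5, 2, 4)]
  expect_equal(omnibus_compare(perm)$F, res$F, tolerance = 1e-10)

  # identical rows: degenerate, no residual variance
  flat <- m; flat[2, ] <- flat[1, ]; flat[3, ] <- flat[1, ]
  expect_true(omnibus_compare(flat)$degenerate)
})

test_that("incomplete subjects are dropped or handled by the mixed model", {
  m <- study_matrix()
  bal <- omnibus_compare(m)  # h055 lacks RSI and is excluded
  expect_equal(bal$n_subjects, 5L)
  expect_true(is.finite(bal$F) && bal$F >= 0)

  unb <- omnibus_compare(m, exclude_incomplete = FALSE)
  expect_equal(unb$n_subjects, 6L)
  expect_true(is.finite(unb$F) && unb$F >= 0)

  # on balanced data the mixed model reproduces the block-ANOVA F
  complete <- m[c("MAD", "MACD", "RSI"),
                colSums(is.na(m[c("MAD", "MACD", "RSI"), ])) == 0]
  both <- omnibus_compare(complete, exclude_incomplete = FALSE)
  expect_equal(both$F, bal$F, tolerance = 1e-6)
})

test_that("paired indicator comparisons reproduce the printed F and difference", {
  m <- study_matrix()
  f5 <- pairwise_compare(m, c("MAD", "MACD"), complete_triples = TRUE)
  expect_equal(f5$n, 5L)
  expect_equal(round_half_up(f5$F, 2), 152.11)
  expect_lt(f5$p, 0.001)

  d6 <- pairwise_compare(m, c("MAD", "MACD"))
  expect_equal(d6$n, 6L)
  expect_equal(round_half_up(d6$mean_diff, 2), 3.17)
  expect_equal(round_half_up(d6$sd_diff, 2), 1.44)

  # the remaining printed pairs, on complete triples
  expect_equal(round(pairwise_compare(m, c("MAD", "RSI"),
                                      complete_triples = TRUE)$F, 2), 3.64)
  expect_equal(round(pairwise_compare(m, c("MACD", "RSI"),
                                      complete_triples = TRUE)$F, 2), 0.61)

  all3 <- pairwise_all(m, complete_triples = TRUE)
  expect_equal(all3$alpha_adjusted, 0.05 / 3)
  expect_named(all3$pairs, c("MAD-MACD", "MAD-RSI", "MACD-RSI"))
})

test_that("paired F equals the squared paired t statistic", {
  m <- study_matrix()
  for (pair in list(c("MAD", "MACD"), c("MAD", "RSI"), c("MACD", "RSI"))) {
    res <- pairwise_compare(m, pair)
    cols <- colSums(is.na(m[pair, ])) == 0
    tt <- stats::t.test(m[pair[1], cols], m[pair[2], cols], paired = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  }
  flat <- matrix(c(1, 1, 2, 2), nrow = 2,
                 dimnames = list(c("MAD", "MACD"), c("a", "b")))
  expect_warning(res <- pairwise_compare(flat, c("MAD", "MACD")),
                 "degenerate")
  expect_true(res$degenerate)
})

test_that("recovery report scores errors, bias, RMSE and failures", {
  truth <- c(100, 100, 100, 100)
  exact <- recovery(truth, truth)
  expect_equal(exact$bias, 0)
  expect_equal(exact$rmse, 0)
  expect_equal(exact$prop_within, 1)

  off <- recovery(truth + 1, truth)
  expect_equal(off$bias, 1)
  expect_equal(off$rmse, 1)

  some <- recovery(c(100, NA, 103, 100), truth, tolerance = 2)
  expect_equal(some$n_not_found, 1L)
  expect_equal(some$prop_within, 0.5)  # the NA and the 3-h miss both fail

  expect_error(recovery(c(1, 2), c(1, 2, 3)), "same length")
})

test_that("recovery studies are reproducible and internally consistent", {
  st1 <- run_recovery_study(n_rep = 4, indicators = c("SMA", "MAD"),
                            seed = 9)
  st2 <- run_recovery_study(n_rep = 4, indicators = c("SMA", "MAD"),
                            seed = 9)
  expect_identical(st1$results, st2$results)
  expect_equal(nrow(st1$results), 8L)
  expect_true(all(st1$results$truth == 113))
  expect_true(all(st1$results$remaining ==
                    168 - st1$results$detected, na.rm = TRUE))
})
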