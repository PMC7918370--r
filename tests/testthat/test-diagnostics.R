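test_that("ACF has value 1 at lag 0 and the closed-form 95% band", {
  set.seed(1)
  a <- acf_series(rnorm(121))
  expect_identical(a$values[1], 1)
  expect_equal(a$band, 1.96 / sqrt(121), tolerance = 1e-12)
  expect_true(all(abs(a$values) <= 1 + 1e-10))
  expect_error(acf_series(rep(2, 50)), "degenerate")
  expect_error(acf_series(c(1, 2)), "too short")
})

test_that("ACF matches the double-loop oracle exactly for short series", {
  set.seed(42)
  for (n in c(8, 13, 20)) {
    y <- rnorm(n)
    a <- acf_series(y, max_lag = n - 2L)
    expect_equal(a$values, acf_oracle(y, n - 2L), tolerance = 1e-12)
  }
})

test_that("ACF is invariant to affine transforms and series reversal", {
  set.seed(7)
  y <- cumsum(rnorm(60))
  a <- acf_series(y, max_lag = 10)
  expect_equal(acf_series(3.7 * y - 2, max_lag = 10)$values, a$values,
               tolerance = 1e-12)
  expect_equal(acf_series(rev(y), max_lag = 10)$values, a$values,
               tolerance = 1e-12)
})

test_that("AR(1) sample ACF approaches phi^k", {
  set.seed(123)
  y <- as.numeric(arima.sim(list(ar = 0.8), 5000))
  a <- acf_series(y, max_lag = 2)
  expect_lt(abs(a$values[2] - 0.8), 0.05)
  expect_lt(abs(a$values[3] - 0.64), 0.05)
})

test_that("whiteness report passes white panels at roughly the nominal rate", {
  set.seed(31)
  resids <- replicate(27, rnorm(121), simplify = FALSE)
  names(resids) <- paste0("s", 1:27)
  rep <- whiteness_report(resids)
  expect_lt(abs(rep$mean_fraction - 0.05), 0.05)
  expect_gte(mean(rep$subjects$pass), 0.8)

  expect_true(whiteness_report(list(s1 = rnorm(121)))$pass)
})

test_that("strong AR(1) residuals fail whiteness with lag 1 flagged everywhere", {
  set.seed(13)
  resids <- replicate(27, as.numeric(arima.sim(list(ar = 0.9), 121)),
                      simplify = FALSE)
  names(resids) <- paste0("s", 1:27)
  rep <- whiteness_report(resids)
  expect_false(rep$pass)
  expect_true(all(vapply(rep$acfs, function(a) 1L %in% a$significant_lags,
                         TRUE)))
})

test_that("KPSS statistic matches an independent implementation on frozen series", {
  set.seed(7)
  ramp <- 0.05 * (1:50) + rnorm(50, 0, 0.3)
  white <- rnorm(60)
  # reference values computed with statsmodels.tsa.stattools.kpss
  # (regression="c") at the same Bartlett truncation lag
  expect_equal(kpss_level(ramp)$statistic, 2.2497071982820946,
               tolerance = 1e-10)
  expect_equal(kpss_level(white)$statistic, 0.10092614898588473,
               tolerance = 1e-10)
  expect_true(kpss_level(ramp)$reject_5pct)
  expect_false(kpss_level(white)$reject_5pct)
})

test_that("trend screen flags a ramp, passes noise, rejects short input", {
  set.seed(5)
  expect_true(trend_flag(0.01 * (1:100) + rnorm(100, 0, 0.05))$flag)
  expect_false(trend_flag(rnorm(100))$flag)
  expect_error(trend_flag(rnorm(5)), "too short")
})
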