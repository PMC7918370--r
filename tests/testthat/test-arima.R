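test_that("differencing order selection removes a ramp and respects the floor", {
  set.seed(17)
  ramp <- 0.05 * (1:100) + rnorm(100, 0, 0.1)
  expect_equal(choose_d(ramp, min_d = 0), 1L)
  white <- rnorm(100)
  expect_equal(choose_d(white, min_d = 1), 1L)
  expect_equal(choose_d(white, min_d = 0), 0L)
  expect_error(choose_d(rnorm(10), min_d = 0), "too short")
})

test_that("a (0,1,0) fit is the naive one-step predictor on a random walk", {
  set.seed(23)
  inc <- rnorm(80)
  rw <- cumsum(inc)
  fit <- fit_arima(rw, arima_order(0, 1, 0))
  expect_equal(fit$fitted[-1], rw[-length(rw)], tolerance = 1e-10)
  expect_equal(fit$residuals[-1], inc[-1], tolerance = 1e-10)
  expect_equal(fit$fitted + fit$residuals, rw, tolerance = 1e-12)
})

test_that("AR and MA coefficients are recovered from long simulated series", {
  set.seed(29)
  ar1 <- as.numeric(arima.sim(list(ar = 0.8), 2000))
  f1 <- fit_arima(ar1, arima_order(1, 0, 0))
  expect_lt(abs(f1$ar_coeffs - 0.8), 0.05)

  ma1 <- as.numeric(arima.sim(list(ma = 0.5), 2000))
  f2 <- fit_arima(ma1, arima_order(0, 0, 1))
  expect_lt(abs(f2$ma_coeffs - 0.5), 0.07)
})

test_that("fitted plus residuals reconstructs the series for assorted orders", {
  set.seed(37)
  y <- as.numeric(arima.sim(list(ar = 0.5, ma = 0.3), 150))
  for (ord in list(c(1, 0, 0), c(0, 1, 1), c(2, 1, 2)))
    expect_equal({ f <- fit_arima(y, ord); f$fitted + f$residuals }, y,
                 tolerance = 1e-12)
})

test_that("degenerate bounds skip the search and seasonal orders are guarded", {
  set.seed(41)
  y <- rnorm(100)
  ord <- stepwise_select(y, d = 1, p_max = 0, q_max = 0)
  expect_equal(c(ord$p, ord$d, ord$q), c(0L, 1L, 0L))
  expect_error(arima_order(1, 0, 0, P = 1), "seasonal period")
  expect_error(arima_order(1, 3, 0))
})

test_that("stepwise selection is within 2 AICc units of exhaustive search", {
  set.seed(43)
  for (rep in 1:3) {
    y <- as.numeric(arima.sim(list(ar = 0.8), 300))
    ord <- stepwise_select(y, d = 0, p_max = 3, q_max = 3)
    expect_gte(ord$p, 1L)
    expect_lte(ord$q, 1L)
    expect_lte(attr(ord, "ic_value"), exhaustive_aicc(y) + 2)
  }
})

test_that("white noise selects the empty model in most seeded replicates", {
  picks <- vapply(1:25, function(s) {
    set.seed(500 + s)
    ord <- stepwise_select(rnorm(300), d = 0)
    ord$p == 0L && ord$q == 0L
  }, TRUE)
  expect_gt(mean(picks), 0.5)
})

test_that("whitening a panel of AR(1)-contaminated residuals restores whiteness", {
  set.seed(47)
  resids <- replicate(6, as.numeric(arima.sim(list(ar = 0.8), 121, sd = 0.04)),
                      simplify = FALSE)
  names(resids) <- paste0("s", 1:6)
  pre <- whiteness_report(resids)
  expect_false(pre$pass)
  fits <- fit_all_residuals(resids, min_d = 1, p_max = 2, q_max = 2)
  expect_true(all(fits$orders$d == 1L))
  expect_lte(fits$whiteness$mean_fraction, 0.10)
  # reconstruction per subject
  for (s in names(resids))
    expect_equal(fits$fits[[s]]$fitted + fits$fits[[s]]$residuals,
                 resids[[s]], tolerance = 1e-12)
})

test_that("residuals that are already white get the trivial model when d is free", {
  set.seed(53)
  resids <- replicate(6, rnorm(150, sd = 0.05), simplify = FALSE)
  names(resids) <- paste0("s", 1:6)
  fits <- fit_all_residuals(resids, min_d = 0, p_max = 2, q_max = 2)
  expect_gte(mean(fits$orders$p == 0 & fits$orders$d == 0 & fits$orders$q == 0),
             0.5)
  expect_error(fit_all_residuals(list()), "no residual series")
})
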