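make_fitted_panel <- function(seed = 61, n_time = 40, noise = "iid",
                              offsets = c(0, 0)) {
  cfg <- sim_config(n_experiments = 1, n_timepoints = n_time, noise = noise,
                    group_offsets = offsets, seed = seed)
  generate_panel(cfg)$panel
}

test_that("naive combination reproduces the trend-model fit exactly", {
  lf <- fit_lmm(make_fitted_panel())
  comb <- combine_fits(lf, mode = "naive")
  expect_true(all(comb$data$arima_fitted == 0))
  expect_equal(comb$data$final_fitted, comb$data$lmm_fitted)
  expect_equal(comb$data$final_fitted + comb$data$residual,
               comb$data$observed, tolerance = 1e-12)
})

test_that("all-zero ARIMA parts make corrected identical to naive", {
  lf <- fit_lmm(make_fitted_panel(seed = 67))
  res <- residual_series(lf)
  zero_fits <- lapply(res, function(r) fit_arima(r, arima_order(0, 0, 0)))
  expect_true(all(vapply(zero_fits, function(f) all(f$fitted == 0), TRUE)))
  co <- combine_fits(lf, zero_fits)
  cn <- combine_fits(lf, mode = "naive")
  expect_equal(co$data$final_fitted, cn$data$final_fitted, tolerance = 1e-12)

  expect_error(combine_fits(lf, zero_fits[-1]), "completeness.*A_e1_r1|completeness")
})

test_that("corrected combination leaves near-zero group residual means", {
  cfg <- sim_config(n_experiments = 1, n_timepoints = 60, seed = 71)
  lf <- fit_lmm(generate_panel(cfg)$panel)
  af <- fit_all_residuals(lf, p_max = 2, q_max = 2)
  comb <- combine_fits(lf, af)
  for (g in names(comb$group_residual_means)) {
    r <- comb$data$residual[comb$data$group == g]
    expect_lt(abs(mean(r)), 2 * stats::sd(r) / sqrt(length(r)))
  }
  expect_equal(comb$data$final_fitted + comb$data$residual,
               comb$data$observed, tolerance = 1e-12)
})

test_that("the timepoint t-test matches the textbook pooled formula", {
  expect_equal(timepoint_test(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  sep <- timepoint_test(c(0, 0, 0, 1e-9), c(1, 1, 1, 1 + 1e-9))
  expect_lt(sep$p, 1e-10)
  set.seed(73)
  a <- rnorm(9); b <- rnorm(9, 1)
  ht <- timepoint_test(a, b)
  expect_equal(ht$t, pooled_t_oracle(a, b), tolerance = 1e-10)
  # degenerate conventions
  expect_equal(timepoint_test(c(2, 2), c(2, 2))$p, 1)
  deg <- timepoint_test(c(2, 2), c(3, 3))
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
  expect_error(timepoint_test(1, c(1, 2)), ">= 2 values")
})

test_that("three groups at alpha 0.05 give the exact Bonferroni threshold", {
  lf <- fit_lmm(make_fitted_panel(seed = 79))
  rep <- pairwise_windows(combine_fits(lf, mode = "naive"), alpha = 0.05)
  expect_equal(rep$threshold, 0.05 / 3, tolerance = 1e-12)
  expect_equal(rep$n_pairs, 3L)
})

test_that("window extraction is a bijection with the run-length oracle", {
  set.seed(83)
  for (i in 1:25) {
    flags <- runif(50) < 0.3
    w <- significance_windows(flags, interval = 2)
    oracle <- runs_oracle(flags)
    expect_equal(nrow(w), length(oracle))
    if (length(oracle)) {
      expect_equal(w$start_index, vapply(oracle, `[`, 0L, 1))
      expect_equal(w$end_index, vapply(oracle, `[`, 0L, 2))
      expect_equal(w$start_minutes, 2 * (w$start_index - 1))
    }
    # every flagged index lies in exactly one window
    covered <- unlist(mapply(seq, w$start_index, w$end_index,
                             SIMPLIFY = FALSE))
    expect_setequal(covered, which(flags))
    expect_equal(anyDuplicated(covered), 0L)
  }
})

test_that("reports are invariant to subject order and group relabeling", {
  p <- make_fitted_panel(seed = 89, noise = "iid")
  comb <- combine_fits(fit_lmm(p), mode = "naive")
  rep1 <- pairwise_windows(comb)

  set.seed(1)
  comb2 <- comb
  comb2$data <- comb2$data[sample(nrow(comb2$data)), ]
  rep2 <- pairwise_windows(comb2)
  expect_equal(rep1$tests$p, rep2$tests$p, tolerance = 1e-12)

  comb3 <- comb
  map <- c(WT = "Z_WT", MUT1 = "A_M1", MUT2 = "B_M2")
  comb3$data$group <- unname(map[comb3$data$group])
  rep3 <- pairwise_windows(comb3)
  expect_setequal(round(rep3$tests$p, 10), round(rep1$tests$p, 10))
})

test_that("a single group cannot be compared", {
  p <- quad_panel(offsets = c(A = 0), noise_sd = 0.05)
  lf <- fit_lmm(p)
  expect_error(pairwise_windows(combine_fits(lf, mode = "naive")),
               "2 groups")
})

test_that("naive and corrected agree on panels with white residuals", {
  p <- make_fitted_panel(seed = 97, n_time = 60, noise = "iid")
  out <- naive_vs_corrected(p, min_d = 0, p_max = 1, q_max = 1)
  expect_gte(mean(out$discordance$agreement), 0.95)
})
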