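test_that("fixed design rows follow the dummy coding with reference all-zero", {
  p <- quad_panel(n_per_group = 2, n_time = 4,
                  offsets = c(A = 0, B = 0.5, C = 1))
  d <- build_design(p)
  expect_identical(colnames(d$X),
                   c("(Intercept)", "Time", "Time2", "groupB", "groupC"))
  ref_row <- d$X[p$group == "A" & p$time == 1, , drop = FALSE][1, ]
  expect_equal(unname(ref_row), c(1, 1, 1, 0, 0))
  b_row <- d$X[p$group == "B" & p$time == 3, , drop = FALSE][1, ]
  expect_equal(unname(b_row), c(1, 3, 9, 1, 0))
  expect_equal(ncol(d$X), 5L)  # three groups -> five fixed coefficients
})

test_that("with no random-effect variance the ML fit matches pooled OLS", {
  p <- quad_panel(n_per_group = 4, n_time = 40, offsets = c(A = 0),
                  noise_sd = 0.05, seed = 11)
  fit <- fit_lmm(p)
  d <- build_design(p)
  ols <- stats::lm.fit(d$X, d$y)$coefficients
  expect_equal(fit$fixed$estimate, unname(ols), tolerance = 1e-4)
})

test_that("fitted plus residual reconstructs the observations", {
  p <- quad_panel(noise_sd = 0.1, seed = 2)
  fit <- fit_lmm(p)
  expect_equal(fit$residuals$fitted + fit$residuals$residual,
               fit$residuals$observed, tolerance = 1e-10)
})

test_that("log-likelihood is invariant to observation order", {
  p <- quad_panel(noise_sd = 0.1, seed = 4)
  fit1 <- fit_lmm(p)
  shuffled <- as.data.frame(p)[sample(nrow(p)), ]
  fit2 <- fit_lmm(as_panel(shuffled))
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-8)
})

test_that("estimated random-effect correlations are valid and BLUPs are centered", {
  cfg <- sim_config(n_experiments = 1, n_timepoints = 40, noise = "iid",
                    seed = 9)
  fit <- fit_lmm(generate_panel(cfg)$panel)
  off <- fit$random_cor[lower.tri(fit$random_cor)]
  expect_true(all(off >= -1 & off <= 1))
  for (k in 1:3)
    expect_lt(abs(mean(fit$blups[, k])), 1e-6 * stats::sd(fit$blups[, k]))
  expect_equal(nrow(fit$blups), 9L)
})

test_that("AIC comparison selects the quadratic over the cubic on quadratic data", {
  cfg <- sim_config(n_experiments = 2, n_timepoints = 60, noise = "iid",
                    seed = 21)
  panel <- generate_panel(cfg)$panel
  quad <- fit_lmm(panel)
  cub <- fit_lmm(panel, include_cubic = TRUE)
  out <- compare_by_aic(list(quad, cub))
  expect_false(out$best$include_cubic)
  expect_equal(out$ranking$model[1], 1L)

  expect_identical(compare_by_aic(list(quad))$best$aic, quad$aic)

  reml <- fit_lmm(panel, reml = TRUE)
  expect_error(compare_by_aic(list(quad, reml)), "comparability")
})

test_that("summary table carries fixed, random and count blocks", {
  p <- quad_panel(noise_sd = 0.1, seed = 5)
  tab <- lmm_summary_table(fit_lmm(p))
  expect_setequal(unique(tab$block), c("fixed", "random", "residual", "counts"))
  expect_equal(tab$estimate[tab$term == "n_obs"], nrow(p))
})
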