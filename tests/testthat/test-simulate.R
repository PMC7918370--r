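test_that("the noiseless limit is the exact deterministic quadratic", {
  cfg <- sim_config(n_groups = 1, group_offsets = numeric(0),
                    replicas_per_experiment = 2, n_experiments = 1,
                    n_timepoints = 15, random_sd = c(0, 0, 0),
                    random_cor = c(0, 0, 0), noise = "iid", noise_sd = 0,
                    seed = 1)
  sim <- generate_panel(cfg)
  t <- 1:15
  expected <- cfg$fixed_effects[1] + cfg$fixed_effects[2] * t +
    cfg$fixed_effects[3] * t^2
  for (s in unique(sim$panel$subject))
    expect_equal(sim$panel$value[sim$panel$subject == s], expected,
                 tolerance = 1e-12)
})

test_that("the full design yields 27 subjects and 3267 observations", {
  sim <- generate_panel(sim_config(seed = 3))
  expect_equal(length(unique(sim$panel$subject)), 27L)
  expect_equal(nrow(sim$panel), 3267L)
  expect_equal(nrow(sim$truth$random_effects), 27L)
})

test_that("AR(1) noise shows the configured lag-1 autocorrelation", {
  cfg <- sim_config(n_groups = 1, group_offsets = numeric(0),
                    replicas_per_experiment = 3, n_experiments = 1,
                    n_timepoints = 2000, random_sd = c(0, 0, 0),
                    random_cor = c(0, 0, 0), fixed_effects = c(0, 0, 0),
                    noise = "ar1", phi = 0.8, seed = 5)
  sim <- generate_panel(cfg)
  lag1 <- vapply(split(sim$panel$value, sim$panel$subject),
                 function(e) acf_series(e, max_lag = 1)$values[2], 0)
  expect_lt(abs(mean(lag1) - 0.8), 0.05)
})

test_that("generation is deterministic given the config", {
  cfg <- sim_config(n_timepoints = 30, seed = 77)
  s1 <- generate_panel(cfg)
  s2 <- generate_panel(cfg)
  expect_identical(s1$panel$value, s2$panel$value)
  expect_identical(s1$truth$random_effects, s2$truth$random_effects)
})

test_that("drawn random effects reproduce the configured covariance", {
  cfg <- sim_config(n_groups = 1, group_offsets = numeric(0),
                    replicas_per_experiment = 400, n_experiments = 1,
                    n_timepoints = 10, noise = "iid", noise_sd = 0.01,
                    seed = 13)
  u <- generate_panel(cfg)$truth$random_effects
  emp <- stats::cov(u)
  expect_equal(stats::cov2cor(emp)[lower.tri(emp)],
               cfg$random_cov[lower.tri(cfg$random_cov)] /
                 (cfg$random_sd[c(2, 3, 3)] * cfg$random_sd[c(1, 1, 2)]),
               tolerance = 0.15)
  expect_equal(unname(sqrt(diag(emp))), cfg$random_sd, tolerance = 0.15)
})

test_that("true difference sets follow the construction", {
  cfg <- sim_config(n_timepoints = 61, seed = 7,
                    group_offsets = c(-0.2, 0),
                    localized_effect = list(group = "MUT2", start_minute = 20,
                                            end_minute = 60, magnitude = 0.3))
  truth <- generate_panel(cfg)$truth
  expect_equal(true_difference_set(truth, c("WT", "MUT1")), 1:61)
  idx <- true_difference_set(truth, c("WT", "MUT2"))
  expect_equal(idx, which(2 * (0:60) >= 20 & 2 * (0:60) <= 60))
  expect_error(true_difference_set(truth, c("WT", "XX")), "unknown pair")

  cfg0 <- sim_config(n_timepoints = 20, group_offsets = c(0, 0), seed = 8)
  truth0 <- generate_panel(cfg0)$truth
  expect_length(true_difference_set(truth0, c("WT", "MUT1")), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(phi = 1.1), "phi")
  expect_error(sim_config(random_cor = c(0.99, -0.99, 0.99)),
               "positive-definite")
})

test_that("operating characteristics are deterministic and carry recovery metrics", {
  cfg <- sim_config(n_groups = 2, group_offsets = 0.5,
                    replicas_per_experiment = 3, n_experiments = 1,
                    n_timepoints = 30, noise = "iid", seed = 19)
  oc1 <- run_operating_characteristics(cfg, n_reps = 2, mode = "naive")
  oc2 <- run_operating_characteristics(cfg, n_reps = 2, mode = "naive")
  expect_identical(oc1$per_rep, oc2$per_rep)
  expect_true(all(c("est_(Intercept)", "tp_rate_naive") %in%
                    names(oc1$per_rep)))
  # constant separation 0.5 >> noise: power should be essentially 1
  expect_gte(mean(oc1$per_rep$tp_rate_naive), 0.9)
})
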