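test_that("environment sampling is deterministic and degenerates cleanly", {
  cfg <- sim_config(n_leaves = 50, seed = 42)
  expect_identical(sample_environment(cfg), sample_environment(cfg))

  # flat envelope + no angle spread + no weather noise -> constant T_leaf
  cfg0 <- sim_config(n_leaves = 30, seed = 1, flat_envelope = TRUE,
                     leaf_angle_sd = 0, par_noise_sd = 0, t_noise_sd = 0)
  env0 <- sample_environment(cfg0)
  expect_equal(diff(range(env0$par_amb)), 0)
  expect_equal(diff(range(env0$t_leaf)), 0)

  expect_error(sim_config(n_leaves = 10, t_corr = 1.2), "t_corr")
  expect_error(sim_config(n_leaves = 0), "n_leaves")
})

test_that("sqrt(PAR)-leaf temperature correlation matches the target", {
  cfg <- sim_config(n_leaves = 2000, seed = 3, t_corr = 0.6)
  env <- sample_environment(cfg)
  expect_lt(abs(cor(sqrt(env$par_amb), env$t_leaf) - 0.6), 0.05)
})

test_that("regime logit is monotone and saturates at covariate extremes", {
  cfg <- sim_config(n_leaves = 10, seed = 1, regime_logit_coeffs = list(
    Model1 = c(-6, 0, 0), Model2 = c(0, 3, 3),
    Model3 = c(0, -3, -3), Intermediate = c(-6, 0, 0)))
  expect_gt(regime_probs(2000, 40, cfg)[, "Model2"], 0.99)
  expect_gt(regime_probs(4, 8, cfg)[, "Model3"], 0.99)

  # all-zero coefficients -> uniform regime frequencies at large n
  cfg_u <- sim_config(n_leaves = 4000, seed = 2, regime_logit_coeffs = list(
    Model1 = c(0, 0, 0), Model2 = c(0, 0, 0),
    Model3 = c(0, 0, 0), Intermediate = c(0, 0, 0)))
  env <- sample_environment(cfg_u)
  reg <- assign_regime(env$par_amb, env$t_leaf, cfg_u, seed = 9)
  freq <- table(reg) / length(reg)
  expect_true(all(abs(freq - 0.25) < 0.03))

  # P(Model2) non-decreasing in T_leaf at fixed PAR, and in PAR at fixed T
  cfg_d <- sim_config(n_leaves = 10, seed = 1)
  p_t <- regime_probs(rep(400, 9), seq(10, 40, length.out = 9), cfg_d)
  expect_false(is.unsorted(p_t[, "Model2"]))
  expect_false(is.unsorted(rev(p_t[, "Model3"])))
  p_p <- regime_probs(seq(10, 2000, length.out = 9), rep(25, 9), cfg_d)
  expect_false(is.unsorted(p_p[, "Model2"]))
})

test_that("empirical regime frequencies track the logit probabilities", {
  cfg <- sim_config(n_leaves = 10, seed = 1)
  n <- 5000
  for (t in c(15, 25, 35)) {
    reg <- assign_regime(rep(400, n), rep(t, n), cfg, seed = t)
    p_hat <- mean(reg == "Model2")
    p <- regime_probs(400, t, cfg)[, "Model2"]
    expect_lt(abs(p_hat - p), 0.03)
  }
})

test_that("noiseless rendering is the exact inverse of derivation", {
  cfg <- sim_config(n_leaves = 25, seed = 5, noise_sd_fluor = 0,
                    noise_sd_ecs = 0)
  sim <- simulate_dataset(cfg)
  rec <- derive_parameters(sim$measurements)
  tr <- truth_for(sim, rec)
  for (ph in c("amb", "high", "rec")) {
    for (p in c("phi2", "npqt", "ql", "ecst", "p700")) {
      col <- paste0(p, "_", ph)
      expect_equal(rec[[col]], tr[[col]], tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
    expect_equal(rec[[paste0("gh_plus_", ph)]], tr$gh_plus,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("planted regimes imprint the predicted sign structure", {
  cfg <- sim_config(n_leaves = 150, seed = 11, noise_sd_fluor = 0,
                    noise_sd_ecs = 0, noise_sd_npq = 0)
  sim <- simulate_dataset(cfg)
  rec <- derive_parameters(sim$measurements)
  tr <- truth_for(sim, rec)
  m3 <- tr$regime == "Model3"
  expect_true(all(rec$ql_high_amb[m3] < 0))
  expect_true(all(rec$p700_high_amb[m3] > 0))
  m2 <- tr$regime == "Model2"
  expect_true(all(rec$ql_high_amb[m2] > 0))
  expect_true(all(rec$npqt_high_amb[m2] > 0))
})

test_that("pathological planting and seed contracts hold", {
  cfg <- sim_config(n_leaves = 100, seed = 7, defect_frac = 0.1,
                    flat_frac = 0.05)
  sim <- simulate_dataset(cfg)
  expect_identical(sum(sim$truth$defective_device), 10L)
  expect_identical(sum(sim$truth$flat_ecs), 5L)
  expect_false(any(sim$truth$defective_device & sim$truth$flat_ecs))
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))

  sim_b <- simulate_dataset(sim_config(n_leaves = 100, seed = 8,
                                       defect_frac = 0.1, flat_frac = 0.05))
  expect_false(identical(sim$measurements$fs_amb, sim_b$measurements$fs_amb))
})

test_that("rendering clamps tiny phi2 and rejects infeasible plantings", {
  cfg <- sim_config(n_leaves = 2, seed = 1, noise_sd_fluor = 0,
                    noise_sd_ecs = 0)
  sim <- simulate_dataset(cfg)
  env <- sample_environment(cfg)
  truth <- sim$truth[1, ]
  truth$phi2_amb <- 0
  expect_warning(m <- render_measurement(truth, env[1, ], cfg, seed = 2),
                 "clamped")
  expect_lt(m$fs_amb, m$fm_prime_amb)

  bad <- sim$truth[1, ]
  bad$ql_high <- 1.7
  expect_error(render_measurement(bad, env[1, ], cfg, seed = 2),
               bad$leaf_id)
})
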