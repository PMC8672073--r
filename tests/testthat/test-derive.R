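test_that("fluorescence estimators evaluate their defining formulas", {
  expect_equal(phi2(400, 1000), 0.6)
  expect_equal(phi2(1000, 1000), 0)
  expect_equal(phi2(0, 123), 1)
  expect_error(phi2(10, 0), "fm_prime")

  expect_equal(lef(0, 1500), 0)
  expect_equal(lef(0.5, 1000, 0.42), 210)
  expect_equal(lef(1, 777, 1), 777)

  expect_equal(npqt(5.88, 1), 0)             # unquenched reference point
  expect_equal(npqt(3, 1), 4.88 / 2 - 1)     # = 1.44
  expect_true(is.na(npqt(1, 1)))             # pole flagged, not returned
  expect_true(is.na(npqt(0.5, 1)))

  expect_equal(ql(300, 1000, 300), 1)        # fs = fo' -> fully open
  expect_equal(ql(1000, 1000, 300), 0)       # fs = fm' -> fully closed
  expect_equal(ql(600, 1000, 300), (400 / 700) * (300 / 600))
  expect_true(is.na(ql(600, 1000, 1000)))    # degenerate denominator
})

test_that("estimator/simulator formula pairs are mutual inverses", {
  withr::with_seed(42, {
    for (i in 1:50) {
      p <- runif(1, 0.02, 0.9)
      nq <- runif(1, 0.05, 8)
      gain <- runif(1, 500, 5000)
      fm <- gain
      fs <- gain * (1 - p)
      fo <- gain * (nq + 1) / (nq + 5.88)
      expect_equal(phi2(fs, fm), p, tolerance = 1e-12)
      expect_equal(npqt(fm, fo), nq, tolerance = 1e-9)
      # the implied qL is the one the estimator recovers
      r <- (nq + 1) / (nq + 5.88)
      ql_implied <- (p * r) / ((1 - p) * (1 - r))
      expect_equal(ql(fs, fm, fo), ql_implied, tolerance = 1e-9)
    }
  })
})

test_that("DIRK fitting recovers exact exponentials and flags flat traces", {
  tr <- make_trace(amplitude = 0.5, rate = 50, offset = 0.1)
  fit <- fit_dirk(tr, "ecs")
  expect_lt(abs(fit$amplitude - 0.5) / 0.5, 1e-6)
  expect_lt(abs(fit$rate - 50) / 50, 1e-6)
  expect_true(is.na(fit$flag))

  # exactly flat trace: no decay to fit, reported as a failed fit
  flat0 <- make_trace(amplitude = 0, rate = 50, offset = 0.1)
  ffit0 <- fit_dirk(flat0, "ecs")
  expect_true(is.na(ffit0$amplitude))
  expect_identical(ffit0$flag, "fit_failed")
  # noisy flat trace: amplitude is unidentified (only amplitude x rate is
  # constrained by drift), so the QC-visible flag is the contract
  flat <- withr::with_seed(33, make_trace(amplitude = 0, rate = 50,
                                          offset = 0.1, noise_sd = 0.003))
  ffit <- fit_dirk(flat, "ecs")
  expect_true(ffit$flag %in% c("low_r2", "low_information", "fit_failed"))

  expect_error(fit_dirk(tibble::tibble(time = c(0, 0.1, 0.05),
                                       value = 1:3)), "increasing")
})

test_that("DIRK fit matches the profile-grid oracle on random traces", {
  withr::with_seed(7, {
    for (i in 1:50) {
      amp <- runif(1, 0.1, 1)
      rate <- runif(1, 10, 100)
      off <- runif(1, -0.1, 0.1)
      tr <- make_trace(amplitude = amp, rate = rate, offset = off,
                       rate_hz = 500)
      fit <- fit_dirk(tr)
      oracle <- grid_fit_dirk(tr)
      expect_lt(abs(fit$amplitude - oracle$amplitude) /
                  abs(oracle$amplitude), 0.01)
      expect_lt(abs(fit$rate - oracle$rate) / oracle$rate, 0.01)
    }
  })
})

test_that("noisy DIRK amplitude errors stay small in Monte Carlo", {
  errs <- withr::with_seed(99, vapply(1:200, function(i) {
    tr <- make_trace(amplitude = 0.5, rate = 20, offset = 0.05,
                     noise_sd = 0.01)
    abs(fit_dirk(tr)$amplitude - 0.5) / 0.5
  }, numeric(1)))
  expect_lt(median(errs), 0.05)
})

test_that("ECSt chlorophyll normalization behaves as a scaling law", {
  expect_equal(normalize_ecst(0.6, 30), 0.02)
  expect_equal(normalize_ecst(0.6, 60), 0.01)
  expect_equal(normalize_ecst(0, 41), 0)
  expect_true(is.na(normalize_ecst(0.6, 0)))
  expect_true(is.na(normalize_ecst(0.6, -3)))
})

test_that("difference columns are exact, antisymmetric subtractions", {
  cfg <- sim_config(n_leaves = 10, seed = 21)
  sim <- simulate_dataset(cfg)
  rec <- derive_parameters(sim$measurements)
  expect_identical(rec$phi2_high_amb, rec$phi2_high - rec$phi2_amb)
  expect_identical(rec$npqt_amb_rec, rec$npqt_amb - rec$npqt_rec)
  expect_identical(rec$ecst_high_rec, rec$ecst_high - rec$ecst_rec)
  expect_identical(rec$sqrt_par, sqrt(rec$par_amb))
  # antisymmetry: swapping the operands flips the sign exactly
  swapped <- rec
  for (p in c("phi2", "npqt", "ql")) {
    a <- swapped[[paste0(p, "_amb")]]
    swapped[[paste0(p, "_amb")]] <- swapped[[paste0(p, "_high")]]
    swapped[[paste0(p, "_high")]] <- a
  }
  swapped <- add_differences(swapped[setdiff(names(swapped),
                                             grep("_high_amb$", names(swapped),
                                                  value = TRUE))])
  expect_identical(swapped$phi2_high_amb, -rec$phi2_high_amb)
})

test_that("identical phases give exactly zero light potentials", {
  cfg <- sim_config(n_leaves = 2, seed = 3, noise_sd_fluor = 0,
                    noise_sd_ecs = 0)
  sim <- simulate_dataset(cfg)
  m <- sim$measurements
  for (col in c("fs", "fm_prime", "fo_prime")) {
    m[[paste0(col, "_high")]] <- m[[paste0(col, "_amb")]]
  }
  rec <- derive_parameters(m)
  expect_identical(rec$phi2_high_amb, rec$phi2_high - rec$phi2_amb)
  expect_equal(rec$phi2_high_amb, rep(0, 2))
  expect_equal(rec$npqt_high_amb, rep(0, 2))
  expect_equal(rec$ql_high_amb, rep(0, 2))
})

test_that("a failed trace fit propagates as missing without losing the rest", {
  cfg <- sim_config(n_leaves = 3, seed = 13)
  sim <- simulate_dataset(cfg)
  m <- sim$measurements
  # corrupt one leaf's ambient ECS trace into pure noise
  m$ecs_trace_amb[[2]] <- tibble::tibble(
    time = m$ecs_trace_amb[[2]]$time,
    value = withr::with_seed(1, rnorm(nrow(m$ecs_trace_amb[[2]]), 0, 0.05)))
  rec <- derive_parameters(m)
  expect_false(is.na(rec$phi2_amb[2]))
  expect_false(is.na(rec$npqt_amb[2]))
  expect_false(is.na(rec$ecs_r2_amb[2]) && is.na(rec$ecs_flag_amb[2]))
  expect_true(!is.na(rec$ecs_flag_amb[2]))
  expect_error(derive_parameters(dplyr::select(m, -"fs_high")), "fs_high")
})
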