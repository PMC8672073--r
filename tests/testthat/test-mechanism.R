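test_that("sign rules map onto the three mechanistic models", {
  expect_identical(classify_point(-0.2, 0.1, margin = 0.02), "Model3_PCON")
  expect_identical(classify_point(0.2, 0.1, margin = 0.02), "Model2_NPQ")
  expect_identical(classify_point(-0.2, -0.1, margin = 0.02),
                   "Model1_PSI_acceptor")
  expect_identical(classify_point(0, 0, margin = 0.02), "Intermediate")
  # fourth quadrant (qL up, P700 down) is predicted by no model
  expect_identical(classify_point(0.2, -0.1), "Intermediate")
  expect_identical(classify_point(NA, 0.1), "Intermediate")
  expect_error(classify_point(0.1, 0.1, margin = -1), "margin")
})

test_that("classification is invariant to positive rescaling of evidence", {
  withr::with_seed(20, {
    ql_d <- runif(100, -0.5, 0.5)
    p_d <- runif(100, -0.5, 0.5)
    for (s in c(0.1, 3, 40)) {
      expect_identical(classify_point(ql_d, p_d, margin = 0.05),
                       classify_point(s * ql_d, s * p_d, margin = s * 0.05))
    }
  })
})

test_that("cluster slopes match OLS exactly and the covariance oracle", {
  # exact linear relation, zero noise -> machine-precision recovery
  d <- tibble::tibble(ecst_high_amb = seq(0.001, 0.02, length.out = 50))
  d$npqt_high_amb <- 0.3 + 35.1 * d$ecst_high_amb
  sl <- suppressWarnings(cluster_slopes(d, rep(1L, 50))) # exact-fit note
  expect_equal(sl$slope, 35.1, tolerance = 1e-12)
  expect_equal(sl$intercept, 0.3, tolerance = 1e-12)

  # closed-form cov/var ratio oracle on noisy clusters
  d2 <- withr::with_seed(21, tibble::tibble(
    ecst_high_amb = runif(80, 0.001, 0.02),
    npqt_high_amb = rnorm(80)))
  sl2 <- cluster_slopes(d2, rep(1L, 80))
  oracle <- cov(d2$ecst_high_amb, d2$npqt_high_amb) / var(d2$ecst_high_amb)
  expect_equal(sl2$slope, oracle, tolerance = 1e-10)

  # degenerate clusters
  one <- cluster_slopes(d[1, ], 1L)
  expect_identical(one$note, "inestimable")
  const <- tibble::tibble(ecst_high_amb = rep(0.01, 10),
                          npqt_high_amb = rnorm(10))
  expect_identical(cluster_slopes(const, rep(1L, 10))$note, "inestimable")
})

test_that("planted per-cluster slopes are recovered with 2-SE coverage", {
  covered <- vapply(1:30, function(s) {
    d <- withr::with_seed(900 + s, {
      x1 <- runif(200, 0.002, 0.02); x2 <- runif(200, 0.002, 0.02)
      tibble::tibble(
        ecst_high_amb = c(x1, x2),
        npqt_high_amb = c(0.1 + 1.6 * x1 + rnorm(200, 0, 0.1),
                          0.1 + 35.1 * x2 + rnorm(200, 0, 0.1)))
    })
    sl <- cluster_slopes(d, rep(1:2, each = 200))
    abs(sl$slope[1] - 1.6) < 2 * sl$slope_se[1] &&
      abs(sl$slope[2] - 35.1) < 2 * sl$slope_se[2]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("the mechanism report summarizes clusters faithfully", {
  cfg <- sim_config(n_leaves = 250, seed = 31)
  sim <- simulate_dataset(cfg)
  rec <- derive_parameters(sim$measurements)
  tr <- truth_for(sim, rec)

  # use the planted regimes as a clustering: majority labels must match
  regimes <- c("Model1", "Model2", "Model3", "Intermediate")
  cl <- as.integer(factor(tr$regime, levels = regimes))
  rep <- mechanism_report(rec, cl)
  for (k in rep$clusters$cluster) {
    reg <- regimes[k]
    if (reg == "Intermediate" || sum(cl == k) < 5) next
    row <- rep$clusters[rep$clusters$cluster == k, ]
    expect_identical(row$majority_label, unname(regime_to_label(reg)))
    expect_gt(row[[paste0("frac_", tolower(reg))]], 0.95)
  }
  m2 <- rep$clusters$cluster == 2
  m3 <- rep$clusters$cluster == 3
  # Model3 leaves live at lower leaf temperature than Model2 leaves
  expect_lt(rep$clusters$t_leaf_median[m3], rep$clusters$t_leaf_median[m2])
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(tidy(rep), "tbl_df")
})

test_that("an all-Model2 dataset is labelled Model2 in every cluster", {
  cfg <- sim_config(n_leaves = 80, seed = 32, regime_logit_coeffs = list(
    Model1 = c(-50, 0, 0), Model2 = c(0, 0, 0),
    Model3 = c(-50, 0, 0), Intermediate = c(-50, 0, 0)))
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$regime == "Model2"))
  rec <- derive_parameters(sim$measurements)
  rep <- mechanism_report(rec, rep_len(1:3, nrow(rec)))
  expect_true(all(rep$clusters$majority_label == "Model2_NPQ"))
})
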