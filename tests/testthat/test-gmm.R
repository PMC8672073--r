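test_that("well-separated planted clusters are recovered exactly", {
  d <- make_two_gaussians(n_per = 200, sep = 6, seed = 1)
  fit <- fit_gmm(d, "y", K = 1:4, n_init = 3, seed = 5)
  expect_identical(fit$K, 2L)
  expect_equal(mclust::adjustedRandIndex(d$label, fit$assignments), 1)
  # responsibilities normalized, loglik monotone
  expect_lt(max(abs(rowSums(fit$responsibilities) - 1)), 1e-8)
  expect_true(all(diff(fit$loglik_trace) >= -1e-10 * abs(fit$loglik)))
  # selected BIC is the optimum of the recorded table
  expect_equal(fit$bic, min(fit$bic_table$bic))
  # clusters ordered by ascending mean sqrt_par
  expect_false(is.unsorted(fit$means[, "sqrt_par"]))
})

test_that("GMM fitting is deterministic given the seed", {
  d <- make_two_gaussians(n_per = 60, sep = 5, seed = 2)
  f1 <- suppressWarnings(fit_gmm(d, "y", K = 1:3, n_init = 2, seed = 11))
  f2 <- suppressWarnings(fit_gmm(d, "y", K = 1:3, n_init = 2, seed = 11))
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$bic_table, f2$bic_table)
})

test_that("one-component fit matches the closed-form Gaussian MLE BIC", {
  d <- make_two_gaussians(n_per = 40, sep = 0, seed = 3)
  fit <- fit_gmm(d, "y", K = 1, families = "full_varying", n_init = 1,
                 seed = 1, standardize = FALSE, ridge = 0)
  expect_true(all(fit$responsibilities == 1))
  X <- as.matrix(d[, c("y", "sqrt_par", "t_leaf")])
  n <- nrow(X); dd <- ncol(X)
  S <- cov(X) * (n - 1) / n
  ch <- chol(S)
  z <- forwardsolve(t(ch), t(X) - colMeans(X))
  ll <- sum(-0.5 * dd * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2))
  p <- dd + dd * (dd + 1) / 2
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  expect_equal(fit$bic, -2 * ll + p * log(n), tolerance = 1e-8)
})

test_that("single-Gaussian data selects K = 1 across seeds", {
  n_sel1 <- sum(vapply(1:25, function(s) {
    d <- withr::with_seed(400 + s, tibble::tibble(
      y = rnorm(50), sqrt_par = rnorm(50, 20, 4), t_leaf = rnorm(50, 25, 3)))
    suppressWarnings(fit_gmm(d, "y", K = 1:6, n_init = 2, seed = s))$K == 1L
  }, logical(1)))
  expect_gte(n_sel1 / 25, 0.95)
})

test_that("the EM agrees with mclust on separated clusters", {
  d <- make_two_gaussians(n_per = 150, sep = 6, seed = 4)
  fit <- fit_gmm(d, "y", K = 1:4, n_init = 3, seed = 2)
  mc <- mclust::Mclust(scale(as.matrix(d[, c("y", "sqrt_par", "t_leaf")])),
                       G = 1:4, verbose = FALSE)
  expect_identical(fit$K, mc$G)
  expect_equal(
    mclust::adjustedRandIndex(fit$assignments, mc$classification), 1)
})

test_that("cluster relabelling leaves ARI and summary sets unchanged", {
  d <- make_two_gaussians(n_per = 100, sep = 6, seed = 6)
  fit <- fit_gmm(d, "y", K = 2, families = "full_varying", n_init = 2,
                 seed = 3)
  perm <- c(2L, 1L)
  relabeled <- perm[fit$assignments]
  expect_equal(mclust::adjustedRandIndex(d$label, relabeled),
               mclust::adjustedRandIndex(d$label, fit$assignments))
  # per-cluster summaries are the same set under relabelling
  dep1 <- within_cluster_dependence(d, fit$assignments, "y",
                                    c("sqrt_par", "t_leaf"))
  dep2 <- within_cluster_dependence(d, relabeled, "y",
                                    c("sqrt_par", "t_leaf"))
  expect_equal(sort(dep1$estimate), sort(dep2$estimate))
})

test_that("broom accessors return well-formed tibbles", {
  d <- make_two_gaussians(n_per = 80, sep = 6, seed = 7)
  fit <- fit_gmm(d, "y", K = 1:3, n_init = 2, seed = 4)
  td <- tidy(fit)
  expect_identical(nrow(td), fit$K * 3L)
  expect_true(all(c("cluster", "weight", "variable", "mean", "sd") %in%
                    names(td)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$K, fit$K)
  au <- generics::augment(fit)
  expect_identical(nrow(au), fit$n)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("assignment transfer keeps labels and recomputes summaries", {
  d <- make_two_gaussians(n_per = 120, sep = 6, seed = 8)
  d$y2 <- d$y
  fit <- fit_gmm(d, "y", K = 1:3, n_init = 2, seed = 5)
  tr <- transfer_assignments(fit, d, "y2")
  expect_identical(tr$assignments[fit$row_index], fit$assignments)
  # identical response -> summaries equal the baseline feature means
  expect_equal(tr$summaries$mean, unname(fit$means[, "y"]), tolerance = 1e-6)
  expect_error(transfer_assignments(fit, d[1:10, ], "y2"), "row identity")
})

test_that("permuting the transferred response destroys covariate dependence", {
  d <- withr::with_seed(10, {
    sq <- c(rnorm(150, 10), rnorm(150, 25))
    tibble::tibble(
      y = c(rnorm(150, 0), rnorm(150, 8)),
      sqrt_par = sq,
      t_leaf = rnorm(300, 25, 3),
      y2 = 2 * sq + rnorm(300, 0, 0.5))
  })
  fit <- fit_gmm(d, "y", K = 2, families = "full_varying", n_init = 2,
                 seed = 6)
  dep <- transfer_assignments(fit, d, "y2")$dependence
  t_orig <- abs(dep$statistic[dep$term == "sqrt_par"])
  d_perm <- d
  d_perm$y2 <- withr::with_seed(11, sample(d$y2))
  dep_p <- transfer_assignments(fit, d_perm, "y2")$dependence
  t_perm <- abs(dep_p$statistic[dep_p$term == "sqrt_par"])
  expect_true(all(t_orig > 10))
  expect_true(all(t_perm < t_orig / 3))
})
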