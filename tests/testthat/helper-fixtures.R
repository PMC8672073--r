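# Shared in-code fixtures; everything is generated at test time.

# mclust serves as the independent cross-check engine; Mclust() needs the
# package attached to resolve its model names.
suppressMessages(library(mclust))

# Two well-separated Gaussian clusters in (response, sqrt_par, t_leaf).
make_two_gaussians <- function(n_per = 200, sep = 6, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    y = c(rnorm(n_per, 0), rnorm(n_per, sep)),
    sqrt_par = c(rnorm(n_per, 12), rnorm(n_per, 12 + sep)),
    t_leaf = rnorm(2 * n_per, 25, 3),
    label = rep(1:2, each = n_per)
  ))
}

# A noiseless exponential DIRK trace.
make_trace <- function(amplitude = 0.5, rate = 50, offset = 0.1,
                       len = 0.3, rate_hz = 1000, noise_sd = 0) {
  t <- seq(0, len, by = 1 / rate_hz)
  tibble::tibble(time = t,
                 value = offset + amplitude * exp(-rate * t) +
                   rnorm(length(t), 0, noise_sd))
}

# Profile-likelihood grid oracle for the exponential DIRK model: for each
# candidate rate the model is linear in (offset, amplitude), so profile a
# rate grid, solve the linear LS exactly, then refine the grid twice.
# Independent of fit_dirk's Levenberg-Marquardt path.
grid_fit_dirk <- function(trace) {
  t <- trace$time; y <- trace$value
  best <- function(rates) {
    rss <- vapply(rates, function(r) {
      X <- cbind(1, exp(-r * t))
      sum(lm.fit(X, y)$residuals^2)
    }, numeric(1))
    rates[which.min(rss)]
  }
  r <- best(exp(seq(log(0.5), log(500), length.out = 120)))
  for (i in 1:3) r <- best(seq(r / 1.5, r * 1.5, length.out = 120))
  X <- cbind(1, exp(-r * t))
  cf <- lm.fit(X, y)$coefficients
  list(offset = cf[[1]], amplitude = cf[[2]], rate = r)
}

# Simulator truth aligned to a derived-record table.
truth_for <- function(sim, records) {
  sim$truth[match(records$leaf_id, sim$truth$leaf_id), ]
}

regime_to_label <- function(regime) {
  c(Model1 = "Model1_PSI_acceptor", Model2 = "Model2_NPQ",
    Model3 = "Model3_PCON", Intermediate = "Intermediate")[regime]
}
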