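#' Configuration for the synthetic leaf-response simulator
#'
#' Builds and validates the configuration object used by
#' [simulate_dataset()] and friends. Defaults encode the measurement
#' protocol (a 10 s step to 2000 umol m-2 s-1, a 10 s far-red dark
#' recovery, ~300 ms DIRK dark intervals) and field-realistic environment
#' statistics (diurnal PAR envelope, leaf-angle modulation, PAR-correlated
#' leaf temperature).
#'
#' @param n_leaves Number of leaves (records) to simulate.
#' @param seed Integer seed; every stochastic draw in the simulator is
#'   reproducible given the config.
#' @param par_high Actinic PAR of the high-light phase (umol m-2 s-1).
#' @param t_high_s,t_dark_s Durations of the high-light and far-red dark
#'   phases (s). Not used numerically by the phenomenological generator but
#'   carried as protocol metadata.
#' @param dirk_len_s Length of the DIRK dark interval (s).
#' @param dirk_rate_hz Sampling rate of the DIRK traces (Hz).
#' @param noise_sd_fluor Relative (multiplicative, log-scale) SD applied
#'   independently to each fluorescence yield.
#' @param noise_sd_ecs Absolute Gaussian SD added to each trace sample
#'   (delta-A units), for both ECS and P700 traces.
#' @param noise_sd_npq Residual SD of NPQ_high around the planted linear
#'   dependence on the light-induced pmf change.
#' @param t_corr Target Pearson correlation between sqrt(PAR_amb) and
#'   leaf temperature; must lie in (-1, 1).
#' @param t_mean,t_sd Mean and SD of leaf temperature (degrees C).
#' @param t_noise_sd Independent weather-noise SD on leaf temperature;
#'   `NULL` (default) chooses `t_sd * sqrt(1 - t_corr^2)` so that the
#'   sample correlation matches `t_corr`.
#' @param par_peak Peak of the diurnal PAR envelope (umol m-2 s-1).
#' @param flat_envelope If `TRUE` the diurnal envelope is constant at
#'   `par_peak` (useful for degenerate tests).
#' @param leaf_angle_sd SD (degrees) of the leaf-angle offset from
#'   sun-normal; `0` disables angle modulation of PAR.
#' @param par_noise_sd Log-scale SD of multiplicative weather noise on PAR.
#' @param regime_logit_coeffs Named list of length-3 numeric vectors
#'   `(intercept, z_tleaf, z_sqrt_par)` for the multinomial logit over the
#'   regimes `Model1`, `Model2`, `Model3`, `Intermediate`; covariates are
#'   standardized as `z_tleaf = (t_leaf - t_mean)/t_sd` and
#'   `z_sqrt_par = (sqrt(par) - 25)/10`.
#' @param slope_model2,slope_model3 Planted sensitivity of NPQ_high-amb to
#'   the normalized pmf change ECSt_high-amb for the rapid-NPQ (Model 2)
#'   and photosynthetic-control (Model 3) regimes. Defaults are the extreme
#'   per-cluster sensitivities reported for field mint data.
#' @param p700_rate_mean Median P700+ re-reduction rate in the dark (s-1).
#' @param device_ids Character vector of (healthy) instrument ids.
#' @param defective_device Id assigned to leaves planted as coming from a
#'   defective instrument.
#' @param defect_frac Fraction of leaves assigned to the defective device.
#' @param flat_frac Fraction of leaves rendered with flat (zero-amplitude)
#'   ECS traces, emulating low-information signals.
#'
#' @return A list of class `lp_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_leaves = 50, seed = 1)
#' cfg$par_high
sim_config <- function(n_leaves = 500,
                       seed = 1L,
                       par_high = 2000,
                       t_high_s = 10,
                       t_dark_s = 10,
                       dirk_len_s = 0.3,
                       dirk_rate_hz = 500,
                       noise_sd_fluor = 0.01,
                       noise_sd_ecs = 0.002,
                       noise_sd_npq = 0.1,
                       t_corr = 0.6,
                       t_mean = 25,
                       t_sd = 5,
                       t_noise_sd = NULL,
                       par_peak = 1800,
                       flat_envelope = FALSE,
                       leaf_angle_sd = 15,
                       par_noise_sd = 0.35,
                       regime_logit_coeffs = NULL,
                       slope_model2 = 35.1,
                       slope_model3 = 1.6,
                       p700_rate_mean = 25,
                       device_ids = sprintf("MSQ%02d", 1:5),
                       defective_device = "MSQ99",
                       defect_frac = 0,
                       flat_frac = 0) {
  if (is.null(regime_logit_coeffs)) {
    regime_logit_coeffs <- list(
      Model1       = c(-3.2, 0, 0),
      Model2       = c(0, 1.2, 1.2),
      Model3       = c(0, -1.2, -1.2),
      Intermediate = c(-1.6, 0, 0)
    )
  }
  cfg <- list(
    n_leaves = as.integer(n_leaves), seed = as.integer(seed),
    par_high = par_high, t_high_s = t_high_s, t_dark_s = t_dark_s,
    dirk_len_s = dirk_len_s, dirk_rate_hz = dirk_rate_hz,
    noise_sd_fluor = noise_sd_fluor, noise_sd_ecs = noise_sd_ecs,
    noise_sd_npq = noise_sd_npq,
    t_corr = t_corr, t_mean = t_mean, t_sd = t_sd, t_noise_sd = t_noise_sd,
    par_peak = par_peak, flat_envelope = isTRUE(flat_envelope),
    leaf_angle_sd = leaf_angle_sd, par_noise_sd = par_noise_sd,
    regime_logit_coeffs = regime_logit_coeffs,
    slope_model2 = slope_model2, slope_model3 = slope_model3,
    p700_rate_mean = p700_rate_mean,
    device_ids = device_ids, defective_device = defective_device,
    defect_frac = defect_frac, flat_frac = flat_frac
  )
  class(cfg) <- "lp_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_leaves < 1L) abort("`n_leaves` must be >= 1.")
  durs <- c(cfg$t_high_s, cfg$t_dark_s, cfg$dirk_len_s)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    abort("all protocol durations must be > 0.")
  }
  if (cfg$dirk_rate_hz <= 0) abort("`dirk_rate_hz` must be > 0.")
  sds <- c(cfg$noise_sd_fluor, cfg$noise_sd_ecs, cfg$noise_sd_npq,
           cfg$par_noise_sd, cfg$leaf_angle_sd)
  if (any(sds < 0)) abort("noise SDs must be >= 0.")
  if (!is.finite(cfg$t_corr) || abs(cfg$t_corr) >= 1) {
    abort("`t_corr` must lie strictly inside (-1, 1).")
  }
  coefs <- cfg$regime_logit_coeffs
  if (!setequal(names(coefs), lp_regimes()) ||
      !all(lengths(coefs) == 3L)) {
    abort("`regime_logit_coeffs` must name Model1, Model2, Model3, Intermediate with 3 coefficients each.")
  }
  if (cfg$defect_frac < 0 || cfg$defect_frac > 1 ||
      cfg$flat_frac < 0 || cfg$flat_frac > 1) {
    abort("`defect_frac` and `flat_frac` must lie in [0, 1].")
  }
  invisible(cfg)
}

lp_regimes <- function() c("Model1", "Model2", "Model3", "Intermediate")

lp_phases <- function() c("amb", "high", "rec")

#' @export
print.lp_sim_config <- function(x, ...) {
  cat("<lp_sim_config>\n")
  cat("  n_leaves:", x$n_leaves, " seed:", x$seed, "\n")
  cat("  protocol: high ", x$par_high, " umol m-2 s-1 for ", x$t_high_s,
      " s; dark ", x$t_dark_s, " s; DIRK ", x$dirk_len_s * 1000,
      " ms @ ", x$dirk_rate_hz, " Hz\n", sep = "")
  cat("  noise: fluor ", x$noise_sd_fluor, " (rel), trace ",
      x$noise_sd_ecs, " (abs)\n", sep = "")
  invisible(x)
}
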