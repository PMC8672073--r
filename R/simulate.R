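#' Sample field environment covariates
#'
#' Draws per-leaf environmental metadata: ambient PAR from a half-sine
#' diurnal envelope modulated by a leaf-angle factor and multiplicative
#' weather noise, and leaf temperature positively correlated with
#' sqrt(PAR_amb) plus independent weather noise.
#'
#' @param cfg A [sim_config()] object.
#' @param seed Seed used for the draw; defaults to `cfg$seed`. Pass `NULL`
#'   to draw from the current RNG state (used internally by
#'   [simulate_dataset()]).
#' @return A tibble with one row per leaf: `leaf_id`, `device_id`,
#'   `timestamp`, `par_amb`, `t_leaf`, `t_ambient`, `leaf_angle`, `lat`,
#'   `lon`.
#' @export
#' @examples
#' env <- sample_environment(sim_config(n_leaves = 20, seed = 3))
#' cor(sqrt(env$par_amb), env$t_leaf)
sample_environment <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, sample_environment(cfg, seed = NULL)))
  }
  n <- cfg$n_leaves
  sunrise <- 6; sunset <- 20
  hour <- runif(n, 5.6, 18.6)
  envelope <- if (cfg$flat_envelope) rep(1, n) else {
    pmax(sin(pi * (hour - sunrise) / (sunset - sunrise)), 0)
  }
  leaf_angle <- pmin(abs(rnorm(n, 0, cfg$leaf_angle_sd)), 80)
  angle_factor <- cos(leaf_angle * pi / 180)
  par_amb <- cfg$par_peak * envelope * angle_factor *
    exp(rnorm(n, 0, cfg$par_noise_sd))
  par_amb <- pmin(pmax(par_amb, 1), cfg$par_high)

  sp <- sqrt(par_amb)
  z <- if (sd(sp) > 0) (sp - mean(sp)) / sd(sp) else rep(0, n)
  t_noise_sd <- cfg$t_noise_sd %||% (cfg$t_sd * sqrt(1 - cfg$t_corr^2))
  t_leaf <- cfg$t_mean + cfg$t_sd * cfg$t_corr * z + rnorm(n, 0, t_noise_sd)
  t_ambient <- t_leaf - 1 + rnorm(n, 0, 0.8)

  base_day <- as.POSIXct("2019-07-21 00:00:00", tz = "UTC")
  day <- sample.int(9, n, replace = TRUE) - 1L

  tibble::tibble(
    leaf_id = sprintf("leaf%05d", seq_len(n)),
    device_id = sample(cfg$device_ids, n, replace = TRUE),
    timestamp = base_day + day * 86400 + hour * 3600,
    par_amb = par_amb,
    t_leaf = t_leaf,
    t_ambient = t_ambient,
    leaf_angle = leaf_angle,
    lat = 42.6734 + rnorm(n, 0, 1e-4),
    lon = -84.4870 + rnorm(n, 0, 1e-4)
  )
}

#' Regime class probabilities and assignment
#'
#' The simulator plants one of four mechanistic response regimes per leaf
#' via a multinomial logit in standardized leaf temperature and
#' sqrt(ambient PAR): `Model2` (rapid NPQ) is favoured at high T_leaf
#' and/or PAR, `Model3` (photosynthetic control) at low values, with rare
#' `Model1` (PSI acceptor limitation) and `Intermediate` leaves.
#'
#' @param par_amb,t_leaf Numeric vectors of covariates (recycled).
#' @param cfg A [sim_config()] object supplying `regime_logit_coeffs`.
#' @return For `regime_probs()`, a matrix of class probabilities (rows sum
#'   to 1); for `assign_regime()`, a character vector of regime labels
#'   drawn from those probabilities.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' regime_probs(1600, 35, cfg)
regime_probs <- function(par_amb, t_leaf, cfg) {
  stopifnot(all(is.finite(par_amb)), all(is.finite(t_leaf)))
  n <- max(length(par_amb), length(t_leaf))
  par_amb <- rep_len(par_amb, n); t_leaf <- rep_len(t_leaf, n)
  zt <- (t_leaf - cfg$t_mean) / cfg$t_sd
  zp <- (sqrt(pmax(par_amb, 0)) - 25) / 10
  eta <- vapply(lp_regimes(), function(r) {
    b <- cfg$regime_logit_coeffs[[r]]
    b[1] + b[2] * zt + b[3] * zp
  }, numeric(n))
  eta <- matrix(eta, nrow = n, dimnames = list(NULL, lp_regimes()))
  eta <- eta - apply(eta, 1, max)
  w <- exp(eta)
  w / rowSums(w)
}

#' @rdname regime_probs
#' @param seed Optional seed for the categorical draw.
#' @export
assign_regime <- function(par_amb, t_leaf, cfg, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, assign_regime(par_amb, t_leaf, cfg)))
  }
  p <- regime_probs(par_amb, t_leaf, cfg)
  u <- runif(nrow(p))
  cum <- t(apply(p, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  lp_regimes()[idx]
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Phi2 implied by a (qL, NPQt) pair: the fluorescence triplet has two
# degrees of freedom up to gain, so the third parameter is determined.
implied_phi2 <- function(ql, npqt) {
  r <- (npqt + 1) / (npqt + 5.88) # Fo'/Fm'
  x <- ql * (1 - r) / r
  x / (1 + x)
}

# Plant ground-truth parameter values for one environment table + regimes.
# Draws from the current RNG state.
plant_truth <- function(env, regime, cfg) {
  n <- nrow(env)
  zp <- sqrt(env$par_amb) / 45
  spad <- clip(rnorm(n, 40, 6), 15, 60)
  gh_plus <- clip(exp(rnorm(n, log(60), 0.25)), 5, 300)
  p700_rate <- exp(rnorm(n, log(cfg$p700_rate_mean), 0.2))

  # Intermediate leaves respond like a 50/50 draw between Model2/Model3.
  branch <- regime
  coin <- runif(n) < 0.5
  branch[regime == "Intermediate"] <-
    ifelse(coin[regime == "Intermediate"], "Model2", "Model3")

  ecs_amp_amb <- (0.08 + 0.45 * zp) * exp(rnorm(n, 0, 0.15))
  d_ecs <- ifelse(branch == "Model1", runif(n, 0, 0.04),
                  runif(n, 0.15, 0.45))
  ecs_amp_high <- ecs_amp_amb + d_ecs
  ecs_amp_rec <- ecs_amp_amb * runif(n, 0.3, 0.7)

  ecst_amb <- ecs_amp_amb / spad
  ecst_high <- ecs_amp_high / spad
  ecst_rec <- ecs_amp_rec / spad

  slope <- dplyr::case_when(
    branch == "Model2" ~ cfg$slope_model2,
    branch == "Model3" ~ cfg$slope_model3,
    TRUE ~ 0
  )
  npqt_amb <- clip(0.25 + 2.0 * zp + rnorm(n, 0, 0.15), 0.05, 6)
  npqt_high <- clip(npqt_amb + slope * (ecst_high - ecst_amb) +
                      rnorm(n, 0, cfg$noise_sd_npq), 0.02, 12)
  npqt_rec <- clip(0.35 * npqt_amb + rnorm(n, 0, 0.05), 0.02, 12)

  ql_amb <- clip(0.30 + 0.25 * zp + 0.01 * (env$t_leaf - cfg$t_mean) +
                   rnorm(n, 0, 0.04), 0.15, 0.72)
  d_ql <- ifelse(branch == "Model2", runif(n, 0.12, 0.28),
                 -runif(n, 0.12, 0.28))
  ql_high <- clip(ql_amb + d_ql, 0.03, 0.97)
  ql_rec <- clip(ql_amb + runif(n, 0.05, 0.15), 0.03, 0.97)

  p700_amb <- clip(0.05 + 0.45 * zp + rnorm(n, 0, 0.03), 0.02, 0.8)
  d_p700 <- ifelse(branch == "Model1", -runif(n, 0.05, 0.15),
                   runif(n, 0.10, 0.30))
  p700_high <- clip(p700_amb + d_p700, 0.02, 1.2)
  # far-red background keeps P700 substantially oxidized in the dark phase
  p700_rec <- runif(n, 0.15, 0.35)

  tibble::tibble(
    leaf_id = env$leaf_id, regime = regime, response_branch = branch,
    spad = spad, gh_plus = gh_plus, p700_rate = p700_rate,
    phi2_amb = implied_phi2(ql_amb, npqt_amb),
    phi2_high = implied_phi2(ql_high, npqt_high),
    phi2_rec = implied_phi2(ql_rec, npqt_rec),
    npqt_amb = npqt_amb, npqt_high = npqt_high, npqt_rec = npqt_rec,
    ql_amb = ql_amb, ql_high = ql_high, ql_rec = ql_rec,
    ecs_amp_amb = ecs_amp_amb, ecs_amp_high = ecs_amp_high,
    ecs_amp_rec = ecs_amp_rec,
    ecst_amb = ecst_amb, ecst_high = ecst_high, ecst_rec = ecst_rec,
    p700_amb = p700_amb, p700_high = p700_high, p700_rec = p700_rec,
    defective_device = FALSE, flat_ecs = FALSE
  )
}

# Render one phase's fluorescence yield triplet from planted (phi2, npqt).
render_fluor <- function(phi2, npqt, gain, sd_rel) {
  if (phi2 < 0.01) {
    warn(sprintf("planted phi2 = %.4g below 0.01; clamped", phi2))
    phi2 <- 0.01
  }
  r <- (npqt + 1) / (npqt + 5.88)
  mult <- function() exp(rnorm(1, 0, sd_rel))
  c(fs = gain * (1 - phi2) * mult(),
    fm_prime = gain * mult(),
    fo_prime = gain * r * mult())
}

render_trace <- function(amp, rate, offset, cfg) {
  t <- seq(0, cfg$dirk_len_s, by = 1 / cfg$dirk_rate_hz)
  tibble::tibble(
    time = t,
    value = offset + amp * exp(-rate * t) + rnorm(length(t), 0, cfg$noise_sd_ecs)
  )
}

#' Render one raw measurement from planted ground truth
#'
#' Inverts the parameter estimators: fluorescence yield triplets are the
#' algebraic inverse of the Phi2/NPQt formulas at the planted values times
#' a random gain (qL is then consistent by construction, see
#' [derive_parameters()]); DIRK traces are
#' `offset + amplitude * exp(-rate * t)` plus Gaussian noise.
#'
#' @param truth One-row ground-truth tibble (see [simulate_dataset()]).
#' @param env One-row environment tibble from [sample_environment()].
#' @param cfg A [sim_config()].
#' @param seed Optional seed; `NULL` draws from the current RNG state.
#' @return A one-row tibble with metadata, per-phase fluorescence yields
#'   (`fs_amb`, `fm_prime_amb`, `fo_prime_amb`, ...), and per-phase DIRK
#'   traces as list-columns of `time`/`value` data frames
#'   (`ecs_trace_amb`, `p700_trace_amb`, ...).
#' @export
render_measurement <- function(truth, env, cfg, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, render_measurement(truth, env, cfg)))
  }
  stopifnot(nrow(truth) == 1L, nrow(env) == 1L)
  for (ph in lp_phases()) {
    ql <- truth[[paste0("ql_", ph)]]
    npq <- truth[[paste0("npqt_", ph)]]
    if (!is.finite(ql) || !is.finite(npq) || ql < 0 || ql > 1 || npq < -1) {
      abort(sprintf("leaf %s: planted values for phase '%s' are outside the invertible range",
                    truth$leaf_id, ph))
    }
  }
  gain <- exp(rnorm(1, log(3000), 0.2))
  out <- dplyr::select(env, -"device_id")
  out$device_id <- if (isTRUE(truth$defective_device)) cfg$defective_device else env$device_id
  out$spad <- truth$spad
  for (ph in lp_phases()) {
    fl <- render_fluor(truth[[paste0("phi2_", ph)]],
                       truth[[paste0("npqt_", ph)]], gain, cfg$noise_sd_fluor)
    out[[paste0("fs_", ph)]] <- fl[["fs"]]
    out[[paste0("fm_prime_", ph)]] <- fl[["fm_prime"]]
    out[[paste0("fo_prime_", ph)]] <- fl[["fo_prime"]]
    ecs_amp <- if (isTRUE(truth$flat_ecs)) 0 else truth[[paste0("ecs_amp_", ph)]]
    out[[paste0("ecs_trace_", ph)]] <- list(render_trace(
      ecs_amp, truth$gh_plus, runif(1, -0.02, 0.02), cfg))
    out[[paste0("p700_trace_", ph)]] <- list(render_trace(
      truth[[paste0("p700_", ph)]], truth$p700_rate, runif(1, -0.02, 0.02), cfg))
  }
  out
}

#' Simulate a ground-truthed light-potential dataset
#'
#' End-to-end generator: samples environments, assigns mechanistic regimes,
#' plants parameter values consistent with each regime's sign structure,
#' and renders raw three-phase measurements. A configurable fraction of
#' leaves is rendered pathological (defective device id and/or flat ECS
#' traces) to exercise downstream QC.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `lp_simulation`: a list with
#'   `$measurements` (raw-measurement tibble, one row per leaf) and
#'   `$truth` (planted ground-truth tibble including the regime label and
#'   pathology indicators).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_leaves = 5, seed = 1))
#' sim$truth$regime
simulate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  withr::with_seed(cfg$seed, {
    env <- sample_environment(cfg, seed = NULL)
    regime <- assign_regime(env$par_amb, env$t_leaf, cfg)
    truth <- plant_truth(env, regime, cfg)

    n <- cfg$n_leaves
    n_defect <- round(cfg$defect_frac * n)
    n_flat <- round(cfg$flat_frac * n)
    if (n_defect + n_flat > n) {
      abort("defect_frac + flat_frac plant more pathological leaves than n_leaves.")
    }
    idx <- sample.int(n, n_defect + n_flat)
    truth$defective_device[idx[seq_len(n_defect)]] <- TRUE
    if (n_flat > 0) truth$flat_ecs[idx[n_defect + seq_len(n_flat)]] <- TRUE

    meas <- purrr::map(seq_len(n), function(i) {
      render_measurement(truth[i, ], env[i, ], cfg)
    })
    meas <- dplyr::bind_rows(meas)
    structure(list(measurements = meas, truth = truth, config = cfg),
              class = "lp_simulation")
  })
}

#' @export
print.lp_simulation <- function(x, ...) {
  cat("<lp_simulation> ", nrow(x$measurements), " leaves (seed ",
      x$config$seed, ")\n", sep = "")
  print(table(x$truth$regime))
  invisible(x)
}
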