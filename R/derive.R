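#' Fluorescence-derived photosynthetic parameters
#'
#' Saturation-pulse estimators applied to one phase's fluorescence yield
#' triplet (steady-state `Fs`, light-adapted maximal `Fm'`, minimal
#' `Fo'`):
#' \describe{
#'   \item{`phi2()`}{PSII quantum efficiency `(Fm' - Fs) / Fm'`.}
#'   \item{`lef()`}{linear electron flow `phi2 * PAR * coeff`, where
#'     `coeff` is leaf absorptivity times the PSII excitation partition
#'     (default `0.42 = 0.84 * 0.5`).}
#'   \item{`npqt()`}{"total NPQ" without a dark-adapted reference,
#'     `4.88 / (Fm'/Fo' - 1) - 1`.}
#'   \item{`ql()`}{fraction of QA in the oxidized ("open") state,
#'     `((Fm' - Fs) / (Fm' - Fo')) * (Fo' / Fs)`.}
#' }
#' All are vectorized. Undefined cases (`Fm' <= Fo'` for `npqt`,
#' degenerate denominators for `ql`) return `NA` so that downstream QC can
#' flag rather than silently drop them; `phi2` with `Fs > Fm'` returns the
#' negative value for the same reason.
#'
#' @param fs,fm_prime,fo_prime Fluorescence yields (arbitrary units).
#' @param phi2 PSII quantum efficiency (fraction).
#' @param par Photon flux (umol photons m-2 s-1).
#' @param coeff Absorptivity x PSII-partition coefficient in (0, 1].
#' @param const Unquenched-reference constant of the total-NPQ estimator.
#' @return Numeric vector.
#' @export
#' @examples
#' phi2(400, 1000)          # 0.6
#' npqt(1000, 1000 / 3)     # Fm'/Fo' = 3 -> 1.44
#' ql(600, 1000, 300)       # 0.2857...
phi2 <- function(fs, fm_prime) {
  if (any(!is.finite(fm_prime)) || any(fm_prime <= 0)) {
    abort("`fm_prime` must be finite and > 0.")
  }
  (fm_prime - fs) / fm_prime
}

#' @rdname phi2
#' @export
lef <- function(phi2, par, coeff = 0.42) {
  stopifnot(all(par >= 0), coeff > 0, coeff <= 1)
  phi2 * par * coeff
}

#' @rdname phi2
#' @export
npqt <- function(fm_prime, fo_prime, const = 4.88) {
  out <- rep(NA_real_, length(fm_prime))
  ok <- is.finite(fm_prime) & is.finite(fo_prime) &
    fo_prime > 0 & fm_prime > fo_prime
  out[ok] <- const / (fm_prime[ok] / fo_prime[ok] - 1) - 1
  out
}

#' @rdname phi2
#' @export
ql <- function(fs, fm_prime, fo_prime) {
  out <- rep(NA_real_, length(fs))
  ok <- is.finite(fs) & is.finite(fm_prime) & is.finite(fo_prime) &
    fs > 0 & fo_prime > 0 & fm_prime > fo_prime
  out[ok] <- ((fm_prime[ok] - fs[ok]) / (fm_prime[ok] - fo_prime[ok])) *
    (fo_prime[ok] / fs[ok])
  out
}

#' Fit dark-interval relaxation kinetics to an exponential decay
#'
#' Nonlinear least-squares fit of `y(t) = offset + amplitude * exp(-rate * t)`
#' to a DIRK trace, used for both the ~520 nm electrochromic-shift decay
#' (amplitude = ECSt before chlorophyll normalization, rate = gH+) and the
#' ~810 nm P700+ re-reduction (amplitude = P700+ oxidation proxy).
#' Initial guesses come from the trace endpoints and a log-linear slope;
#' the rate is bounded below by zero.
#'
#' @param trace A data frame with numeric columns `time` (strictly
#'   increasing, s) and `value`.
#' @param kind `"ecs"` or `"p700"`; recorded in the output.
#' @param r2_floor Fits with R-squared below this value are flagged
#'   `"low_r2"` (they are returned, not dropped).
#' @return A one-row tibble: `kind`, `amplitude`, `rate`, `offset`, `r2`,
#'   `resid_sd`, `n`, `flag` (`NA` for a clean fit, otherwise one of
#'   `"fit_failed"`, `"low_information"`, `"low_r2"`).
#' @export
#' @examples
#' t <- seq(0, 0.3, by = 0.002)
#' tr <- data.frame(time = t, value = 0.1 + 0.5 * exp(-50 * t))
#' fit_dirk(tr)
fit_dirk <- function(trace, kind = c("ecs", "p700"), r2_floor = 0.5) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(trace), all(c("time", "value") %in% names(trace)))
  t <- trace$time; y <- trace$value
  if (length(t) < 4L || any(diff(t) <= 0)) {
    abort("DIRK trace needs >= 4 samples with strictly increasing time.")
  }
  n <- length(t)
  n_tail <- max(3L, ceiling(0.1 * n))
  off0 <- mean(y[(n - n_tail + 1L):n])
  amp0 <- mean(y[seq_len(n_tail)]) - off0
  # log-linear slope for the rate guess, guarded against non-positive args
  rate0 <- {
    z <- y - off0
    if (amp0 > 0 && sum(z > amp0 * 0.05) >= 3L) {
      keep <- z > amp0 * 0.05
      sl <- -coef(lm(log(z[keep]) ~ t[keep]))[[2]]
      if (is.finite(sl) && sl > 0) sl else 3 / max(t)
    } else 3 / max(t)
  }
  if (!is.finite(amp0)) amp0 <- 0

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ offset + amplitude * exp(-rate * t),
      start = list(offset = off0, amplitude = amp0, rate = rate0),
      lower = c(offset = -Inf, amplitude = -Inf, rate = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    return(tibble::tibble(kind = kind, amplitude = NA_real_, rate = NA_real_,
                          offset = NA_real_, r2 = NA_real_,
                          resid_sd = NA_real_, n = n, flag = "fit_failed"))
  }
  cf <- coef(fit)
  res <- y - predict(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  flag <- NA_character_
  if (!is.finite(r2)) flag <- "low_information"
  else if (r2 < r2_floor) flag <- "low_r2"
  tibble::tibble(kind = kind, amplitude = cf[["amplitude"]],
                 rate = cf[["rate"]], offset = cf[["offset"]], r2 = r2,
                 resid_sd = sd(res), n = n, flag = flag)
}

#' Normalize an ECS amplitude by relative chlorophyll content
#'
#' Divides the raw DIRK amplitude by the SPAD reading to account for
#' differences in leaf thickness, light path, and chloroplast number, so
#' ECSt is comparable across leaves.
#'
#' @param amplitude Raw ECS DIRK amplitude (delta-A units).
#' @param spad SPAD relative chlorophyll content; non-positive values
#'   yield `NA`.
#' @return `amplitude / spad`, vectorized.
#' @export
normalize_ecst <- function(amplitude, spad) {
  out <- amplitude / spad
  out[!is.finite(spad) | spad <= 0] <- NA_real_
  out
}

lp_params <- function() c("phi2", "lef", "npqt", "ql", "ecst", "gh_plus", "p700")

#' Derive light-potential records from raw measurements
#'
#' For every leaf and protocol phase (`amb`, `high`, `rec`) this computes
#' the fluorescence parameters (Phi2, LEF, NPQt, qL), fits both DIRK
#' traces (ECSt + gH+ from the electrochromic shift; P700+ amplitude at
#' 810 nm), normalizes ECSt by SPAD, and assembles all pairwise
#' light-potential differences `X_high_amb`, `X_amb_rec`, `X_high_rec`
#' together with `sqrt_par = sqrt(par_amb)`. Failed or undefined sub-fits
#' propagate as `NA`; diagnostics (`ecs_r2_*`, `p700_r2_*`, fit flags) are
#' retained for QC.
#'
#' LEF uses the phase-appropriate photon flux: `par_amb` for the ambient
#' phase, `par_high` for the high-light phase, and 0 for the far-red dark
#' recovery.
#'
#' @param measurements Raw-measurement tibble as produced by
#'   [simulate_dataset()] or [read_photosynq()] (trace list-columns
#'   `ecs_trace_*`, `p700_trace_*`).
#' @param lef_coeff Absorptivity x PSII-partition coefficient.
#' @param npqt_const Reference constant of the total-NPQ estimator.
#' @param par_high Photon flux of the high-light phase (umol m-2 s-1).
#' @param r2_floor Passed to [fit_dirk()].
#' @return A tibble with one row per leaf: metadata, per-phase parameters
#'   (`phi2_amb`, ..., `p700_rec`), fit diagnostics, and all difference
#'   columns.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_leaves = 3, seed = 1))
#' rec <- derive_parameters(sim$measurements)
#' rec[, c("phi2_amb", "npqt_high_amb", "ql_high_amb")]
derive_parameters <- function(measurements, lef_coeff = 0.42,
                              npqt_const = 4.88, par_high = 2000,
                              r2_floor = 0.5) {
  req <- c("leaf_id", "par_amb", "spad",
           paste0("fs_", lp_phases()), paste0("fm_prime_", lp_phases()),
           paste0("fo_prime_", lp_phases()))
  miss <- setdiff(req, names(measurements))
  if (length(miss)) {
    abort(paste0("missing required columns: ", paste(miss, collapse = ", ")))
  }
  meta_cols <- intersect(
    c("leaf_id", "device_id", "timestamp", "par_amb", "t_leaf", "t_ambient",
      "leaf_angle", "lat", "lon", "spad"), names(measurements))
  out <- dplyr::as_tibble(measurements[meta_cols])
  out$sqrt_par <- sqrt(out$par_amb)

  par_phase <- list(amb = measurements$par_amb,
                    high = rep(par_high, nrow(measurements)),
                    rec = rep(0, nrow(measurements)))

  for (ph in lp_phases()) {
    fs <- measurements[[paste0("fs_", ph)]]
    fm <- measurements[[paste0("fm_prime_", ph)]]
    fo <- measurements[[paste0("fo_prime_", ph)]]
    out[[paste0("phi2_", ph)]] <- phi2(fs, fm)
    out[[paste0("lef_", ph)]] <- lef(out[[paste0("phi2_", ph)]],
                                     par_phase[[ph]], lef_coeff)
    out[[paste0("npqt_", ph)]] <- npqt(fm, fo, npqt_const)
    out[[paste0("ql_", ph)]] <- ql(fs, fm, fo)
    # carry raw yields for range QC (fm' > fs rule)
    out[[paste0("fs_", ph)]] <- fs
    out[[paste0("fm_prime_", ph)]] <- fm

    ecs_col <- measurements[[paste0("ecs_trace_", ph)]]
    p700_col <- measurements[[paste0("p700_trace_", ph)]]
    if (!is.null(ecs_col)) {
      fits <- purrr::map(ecs_col, fit_dirk, kind = "ecs", r2_floor = r2_floor)
      fits <- dplyr::bind_rows(fits)
      out[[paste0("ecst_", ph)]] <- normalize_ecst(fits$amplitude,
                                                   measurements$spad)
      out[[paste0("gh_plus_", ph)]] <- fits$rate
      out[[paste0("ecs_r2_", ph)]] <- fits$r2
      out[[paste0("ecs_flag_", ph)]] <- fits$flag
    }
    if (!is.null(p700_col)) {
      fits <- purrr::map(p700_col, fit_dirk, kind = "p700", r2_floor = r2_floor)
      fits <- dplyr::bind_rows(fits)
      out[[paste0("p700_", ph)]] <- fits$amplitude
      out[[paste0("p700_r2_", ph)]] <- fits$r2
      out[[paste0("p700_flag_", ph)]] <- fits$flag
    }
  }
  add_differences(out)
}

#' Append light-potential difference columns
#'
#' Computes `X_high_amb = X_high - X_amb`, `X_amb_rec = X_amb - X_rec`
#' and `X_high_rec = X_high - X_rec` for every derived parameter present
#' in all three phases. Exported so that pass-through tables (derived
#' parameters without raw traces) can be completed the same way.
#'
#' @param records A tibble with per-phase parameter columns.
#' @return The tibble with difference columns (and `sqrt_par` if
#'   `par_amb` is present) appended.
#' @export
add_differences <- function(records) {
  if (!"sqrt_par" %in% names(records) && "par_amb" %in% names(records)) {
    records$sqrt_par <- sqrt(records$par_amb)
  }
  pairs <- list(c("high", "amb"), c("amb", "rec"), c("high", "rec"))
  for (p in lp_params()) {
    for (pr in pairs) {
      a <- paste0(p, "_", pr[1]); b <- paste0(p, "_", pr[2])
      if (all(c(a, b) %in% names(records))) {
        records[[paste0(p, "_", pr[1], "_", pr[2])]] <-
          records[[a]] - records[[b]]
      }
    }
  }
  records
}
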