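---
title: "Methods: deriving, clustering and classifying photosynthetic light potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving, clustering and classifying photosynthetic light potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lightpotential)
```

## The measurement and its observables

A light-potential measurement clamps one leaf and records optical signals
in three phases: at ambient PAR, after a 10 s step to 2000 µmol m⁻² s⁻¹
(full-sunlight equivalent), and after 10 s of darkness under weak far-red
light. Each phase yields a fluorescence triplet (steady-state Fs,
light-adapted maximal Fm′, minimal Fo′) and two dark-interval relaxation
kinetics (DIRK) traces over a ~300 ms dark window: the ~520 nm
electrochromic shift (ECS), whose decay amplitude is a relative measure of
thylakoid proton motive force (pmf) and whose rate constant estimates the
ATP-synthase proton conductivity g_H⁺; and the ~810 nm absorbance change
tracking P700⁺ re-reduction, whose amplitude is a relative measure of PSI
donor oxidation.

From the triplet we compute Φ_II = (Fm′ − Fs)/Fm′, LEF = Φ_II · PAR ·
*c*, NPQt = 4.88/(Fm′/Fo′ − 1) − 1, and qL = ((Fm′ − Fs)/(Fm′ − Fo′)) ·
(Fo′/Fs). The LEF coefficient *c* defaults to 0.42 (0.84 leaf absorptivity
× 0.5 PSII excitation partition) and is configurable; it is a convention,
not a measured quantity, and only scales LEF. NPQt's constant 4.88 is the
reference value of the rapid total-NPQ method, which requires no
dark-adapted baseline — appropriate for survey measurements where
dark-adaptation is impossible. Each phase uses its own Fo′; the far-red
phase supplies the recovery Fo′. The "light potential" of any parameter X
is the phase difference, primarily X_high−amb; the package also forms
X_amb−rec and X_high−rec. Analyses and plots use √PAR because it spreads
the ecologically dense low-light range and partially linearizes light
responses.

**Assumptions.** The estimators assume the saturation pulse fully closes
PSII (Fm′ is maximal), that the DIRK decays are single-exponential with a
free offset over the 300 ms window, and that SPAD is an adequate
per-leaf proxy for the optical path of the ECS signal (only ECSt is
SPAD-normalized; P700⁺ is reported in raw ΔA units because its optical
cross-section is not chlorophyll-limited in the same way).

## DIRK fitting

`fit_dirk()` fits y(t) = offset + amplitude·exp(−rate·t) by
Levenberg–Marquardt nonlinear least squares. Initial guesses come from the
trace endpoints (offset from the final 10%, amplitude from the initial
10%) and a log-linear regression of the early decay for the rate, with a
fallback of 3/t_max when the log-linear slope is unusable. The rate is
bounded below by zero. Fits report R² and residual SD; non-convergent fits
return `NA` with a `fit_failed` flag, zero-variance traces return
`low_information`, and R² below a configurable floor (default 0.5) returns
`low_r2`. Failed sub-fits propagate as missing values with their reasons —
no imputation anywhere in the pipeline.

## Quality control

QC rules are declarative data (YAML-serializable), not code: theoretical
ranges (Φ_II and qL in [0, 1], NPQt in [−0.1, 15], ECSt ≥ 0, g_H⁺ in
(0, 500] s⁻¹), DIRK fit quality (R² ≥ 0.5, with missing/low-information
fits counting as violations), fluorescence ordering (Fm′ > Fs), and device
blacklists. Flags carry a rule id, reason and severity; `apply_qc()`
builds an analysis view that drops exclude-flagged rows but the full table
is always preserved. Range rules flag values, never mutate them.

## Gaussian mixture clustering

Responses are clustered jointly with √PAR_amb and leaf temperature using
Gaussian mixtures fitted by expectation–maximization. Six covariance
families are tried — {spherical, diagonal, full} × {equal, varying} — and
component counts over a user range (default 1–8, capped at 12). Model
selection minimizes BIC = −2·loglik + p·log(n), where p counts mixing
weights (K − 1), means (K·d) and the family's covariance parameters. Ties
prefer smaller K, then the simpler family in the lattice order above.

Numerical choices, in full:

* **Standardization.** Features are z-scored before EM by default; centers
  and scales are stored so reported cluster means are on the original
  scale. Without it the covariates (°C, √µmol units) would dominate the
  likelihood geometry arbitrarily.
* **Initialization.** Each candidate gets `n_init` starts: k-means++
  distance-weighted seeding followed by a short Lloyd refinement, then a
  hard-assignment M-step. Raw k-means++ seeds gravitate toward outlying
  points and can start EM next to a singleton component; the Lloyd pass
  re-balances the initial partition.
* **Convergence.** EM stops when the relative log-likelihood change falls
  below 10⁻⁸ or at 500 iterations. The log-likelihood trace is stored and
  asserted non-decreasing (to 10⁻¹⁰ relative slack) on every fit in the
  test suite.
* **Degeneracy.** The mixture likelihood is unbounded: a component can
  collapse onto a few points with vanishing variance. Solutions are
  rejected when any component's effective size falls below d + 1 during
  EM, or when a final covariance eigenvalue falls below 10⁻⁴ on the
  standardized scale (a cluster with SD < 1% of the data spread is not a
  meaningful environmental regime). Covariances carry a small ridge
  (10⁻⁸); candidates that still fail are dropped with a warning and simply
  do not compete in the BIC table.
* **Labels.** MAP assignments break responsibility ties toward the lowest
  cluster index, and clusters are relabelled by ascending mean √PAR so
  that cluster numbering is reproducible and roughly tracks the light
  gradient.

`transfer_assignments()` freezes a baseline clustering configuration
(e.g. from NPQ_amb) and recomputes per-cluster summaries and OLS covariate
dependencies on another response, which is how intercluster changes in
environmental control are compared across responses.
`within_cluster_dependence()` reports per-cluster OLS coefficients with
explicit `untestable` (n < 5), `zero_variance` and `inestimable`
(rank-deficient) notes. `subsample_robustness()` refits on random
subsamples and scores agreement with the full-data clustering by adjusted
Rand index. `fit_linear_effects()` provides the whole-table
response ~ √PAR × T_leaf baseline model.

## Mechanistic classification

Upon a step to high light, three limitations predict distinct sign
patterns in the evidence plane (qL_high−amb, P700⁺_high−amb):

| Model | qL_high−amb | P700⁺_high−amb | Interpretation |
|---|---|---|---|
| 1 | < 0 | < 0 | PSI acceptor-side limitation: electrons back up everywhere |
| 2 | > 0 | > 0 | rapid NPQ: excitation to PSII is throttled, chain oxidizes |
| 3 | < 0 | > 0 | photosynthetic control at cyt b₆f without qE: Q_A reduces, PSI oxidizes |

The fourth quadrant is predicted by no model and maps, together with a
configurable dead-zone margin around zero (default 0), to
`Intermediate`. Classification is a pure function of the two signs given
the margin, hence scale-invariant under positive rescaling of both axes.
Both point-level labels and cluster-level majority labels are reported,
since mechanistic reasoning is most robust at cluster level. The qE/PCON
balance is quantified as the per-cluster OLS slope (with intercept — the
ambient NPQ level need not extrapolate through zero) of NPQ_high−amb on
ECSt_high−amb, with its standard error.

## The synthetic-leaf simulator

`simulate_dataset()` generates ground-truthed campaigns so that every
stage has a planted oracle. It emulates, phenomenologically:

* **Environment.** Sampling hours over a field day, PAR from a half-sine
  diurnal envelope (sunrise 06:00, sunset 20:00) modulated by a
  cos(leaf-angle) factor (angle offsets ~ |N(0, 15°)|) and multiplicative
  log-normal weather noise; leaf temperature built from standardized
  √PAR with target correlation 0.6 plus independent weather noise
  (SD chosen so the sample correlation matches the target), mean 25 °C,
  SD 5 °C — representative of a temperate mid-summer campaign.
* **Regimes.** A multinomial logit over (standardized T_leaf, √PAR)
  assigns each leaf Model 1 (rare, intercept −3.2), Model 2 (favoured
  warm/bright, slopes +1.2), Model 3 (favoured cool/dim, slopes −1.2) or
  Intermediate (intercept −1.6). P(Model 2) is monotone non-decreasing in
  both covariates by construction. Intermediate leaves draw their response
  from Model 2 or Model 3 rules with equal probability.
* **Responses.** Planted NPQt and qL per phase carry the regime's sign
  structure; ECSt amplitudes rise with √PAR with regime-dependent
  high−amb increments (suppressed for Model 1); NPQ_high follows
  NPQ_amb + slope·ECSt_high−amb with planted sensitivities 35.1
  (Model 2) and 1.6 (Model 3) — the extreme per-cluster values estimated
  for field mint data — plus residual SD 0.1. The far-red recovery phase
  keeps P700 substantially oxidized (amplitude 0.15–0.35), as far-red
  preferentially excites PSI.
* **Signals.** Fluorescence triplets invert the Φ_II and NPQt estimators
  at the planted values times a random per-leaf gain, with independent
  multiplicative noise (relative SD 0.01) per yield. DIRK traces are exact
  exponentials at the planted amplitude and rate plus additive Gaussian
  noise (SD 0.002 ΔA) sampled at 500 Hz over 300 ms. Configurable
  fractions of leaves are planted pathological: assigned to a defective
  device id, or rendered with flat (zero-amplitude) ECS traces.

One structural point deserves emphasis: a fluorescence triplet has only
two degrees of freedom up to gain, so Φ_II, NPQt and qL cannot be planted
independently. The simulator plants NPQt and qL — the two quantities whose
sign and slope structure the mechanistic regimes constrain — and derives
the implied Φ_II = x/(1 + x) with x = qL·(1 − r)/r, r = (Fo′/Fm′) =
(NPQt + 1)/(NPQt + 5.88). The implied Φ_II values land in the physically
sensible 0.02–0.85 range for the planted parameter ranges. Planted Φ_II
below 0.01 (which would make Fs ≥ Fm′) is clamped with a logged warning;
planted values outside the invertible range are rejected with the leaf id.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: no biophysical model of thylakoid ion fluxes or
lumen pH (responses are planted at the level of the observables); no
within-leaf heterogeneity, no canopy-position effects, no diurnal
hysteresis or acclimation memory; no multi-exponential or drifting DIRK
baselines; no instrument gain-settling dynamics; noise is Gaussian and
uncorrelated across yields and trace points. Real field data will violate
several of these, which is why QC thresholds and the GMM family lattice
are configurable rather than fixed.

## Validation conditions and known limitations

The test suite and the acceptance script validate at sizes chosen to
exercise each property well inside a desktop minute-to-minutes budget: 200
noiseless leaves for the round-trip identity (machine precision, asserted
at 10⁻⁶), 200 Monte-Carlo replicates for noisy DIRK recovery (median
amplitude error < 5% at noise SD 0.01, amplitude 0.5), n = 400 planted
two-component mixtures at 6-SD separation (K = 2, ARI = 1 required),
100 seeds of n = 50 single Gaussians (K = 1 in ≥ 95%), the default
n = 1000 simulated campaign for classification accuracy (≥ 95% against
planted regimes) and cluster-level T_leaf ordering, and quarter
subsamples of well-separated clusterings (median ARI ≥ 0.9).

Classification accuracy is scored over leaves planted as Models 1–3;
Intermediate leaves draw their responses from a mixture and have no
well-defined target region, so they are excluded from the accuracy
denominator (they are still simulated, classified and reported).

Known limitations: the GMM assumes ellipsoidal clusters and can split
strongly non-Gaussian regimes; BIC selection on small n is conservative by
design; the sign-based classifier ignores magnitude information beyond the
dead zone, so measurement noise near the axes maps to `Intermediate`
rather than to a forced model call; and the per-cluster slopes are plain
OLS — errors-in-variables in ECSt_high−amb will attenuate them slightly
relative to the planted sensitivities.
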