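---
title: "Methods: sensor-based tremor severity from spiral drawing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-based tremor severity from spiral drawing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Essential tremor (ET) is an action tremor with power concentrated in the
4--12 Hz band; clinical severity is conventionally rated on the
Fahn--Tolosa--Marin (FTM) scale, which includes an Archimedes-spiral drawing
task. This package quantifies the same drawing task instrumentally, from two
streams recorded simultaneously:

* a digitizing-tablet pen stream `(t, x, y, pressure)`, where pressure = 0
  marks the pen held above the tablet, and
* triaxial accelerometer streams `(t, ax, ay, az)` from up to three arm
  sites (S1 hand dorsum, S2 mid-forearm, S3 upper arm), nominally sampled
  at 148.1 Hz.

Two features are derived per subject and site. The **task time** $T$ is the
total pen-down duration. The **PSD ratio** $\rho$ is the integrated power
spectral density of the high-pass-filtered acceleration vector magnitude in
the tremor band (4--12 Hz) divided by that in the voluntary-movement band
(0.5--4 Hz). Severity is then estimated by ordinary least squares,
canonically the bivariate model

$$\widehat{FTM} = \beta_0 + \beta_1 T + \beta_2 \rho,$$

available with fixed published coefficients $(8.2439,\ 0.2791,\ 1.9890)$
through `published_ftm_model()`, and phenotype (control / ET$-$0 / ET$+1$ /
ET$+2$) is classified by a leave-one-out cross-validated SVM.

## Feature path and its assumptions

1. **Segmentation.** The task window runs from the first to the last
   pen-down sample. $T$, however, counts only pen-down samples, so pen lifts
   inside the task extend the window but not $T$. These two conventions are
   deliberately different: the accelerometer is analysed over the whole
   task, while $T$ is the drawing duration proper. The accelerometer slice
   uses the closed interval $[t_\mathrm{start}, t_\mathrm{end}]$ after
   applying a configurable constant pen-to-IMU clock offset (default 0; the
   two streams are assumed to share a clock, as with an integrated
   acquisition system).
2. **Vector magnitude.** $m = \sqrt{a_x^2 + a_y^2 + a_z^2}$ is invariant
   under rotation of the sensor frame, so results do not depend on strap
   orientation. The cost is a nonlinearity: with gravity $g$ on one axis and
   dynamic acceleration small relative to $g$, $m \approx g + a_\parallel$,
   the component along gravity. Orientation invariance is asserted in the
   test suite to $10^{-6}$ relative under random rotations.
3. **High-pass filter.** A 4th-order Butterworth at 0.5 Hz, applied forward
   and backward (zero phase, effective 8th-order roll-off), removes the
   gravity offset embedded in the magnitude and slow drift. Edge handling
   uses odd-reflection padding (about three cutoff periods) with
   steady-state initial conditions, so a constant input is rejected
   essentially to machine precision and short clinical recordings do not
   inherit start-up transients. Signals shorter than about three filter
   lengths are refused rather than silently filtered.
4. **Spectral estimate.** Welch's method: Hann window, 4-s segments
   (0.25 Hz resolution, enough to resolve the 0.5 Hz band edge), 50%
   overlap, per-segment mean detrending, one-sided density scaling. Signals
   shorter than one segment fall back to a single-segment periodogram with
   a warning. Band power is the trapezoidal integral of the density over
   the band; the ratio of two such integrals is dimensionless and invariant
   to uniform scaling of the signal, which is what makes $\rho$ comparable
   across subjects, sensors and units (g vs m/s$^2$). Whether the original
   analysis used Welch or a plain periodogram is not stated anywhere we
   could find; the Welch parameters are exposed in the configuration and
   the estimator is validated against analytic sinusoid variances and a
   direct periodogram-summation oracle.
5. **Band edges.** The voluntary band is $[0.5, 4)$ Hz and the tremor band
   $[4, 12]$ Hz, so a tone exactly at 4 Hz belongs to the tremor band by
   convention. Numerically the trapezoidal integral splits a boundary tone
   between the adjacent bands; the synthetic generator keeps tremor
   frequencies in $[4.5, 11.5]$ Hz so no tested quantity depends on the
   boundary convention.

## Severity models and statistics

`ftm_severity()` fits FTM on `task_time` and/or `psd_ratio` by OLS
(`stats::lm` underneath) and reports $r^2$ and RMSE. RMSE uses the
population convention $\sqrt{SSE/n}$ by default (`rmse_df_correct = TRUE`
gives $\sqrt{SSE/(n-p)}$); the convention is documented because published
RMSE values rarely state theirs. Predictions are clipped at 0, since an FTM
score cannot be negative. Constant or collinear predictors raise a
collinearity error rather than returning a rank-deficient fit.

The group-comparison layer is deliberately nonparametric: Shapiro--Wilk is
computed as a report-only gate (drawing features are not expected to be
Gaussian), groups are compared with Mann--Whitney U and Kruskal--Wallis.
The reported U statistic is $\min(U_a, U_b)$, which is symmetric in the
group order and matches the convention under which small printed values of
U indicate strong separation. Exact enumeration is used when both groups
have at most 8 untied observations; otherwise the tie-corrected normal
approximation with continuity correction. No multiple-testing correction is
applied by default, matching the single-table reporting style this package
mirrors; `stats::p.adjust` can be applied downstream if desired.

## Phenotype classification

`loocv_accuracy()` implements leave-one-out cross-validation around
`e1071::svm` (C-classification, one-vs-one multiclass). Three protocol
details matter at $n \approx 35$:

* **Per-fold standardisation.** Task time (seconds) and PSD ratio
  (dimensionless) are incommensurate; each training fold's mean/SD are
  computed without the held-out instance and applied to it. This is the
  no-leakage property the test suite checks explicitly.
* **Fixed hyperparameters.** $C = 1$ and, for the RBF kernel,
  $\gamma = 1/d$ on standardised features (the variance-scaled rule).
  Small-sample LOOCV is sensitive to these, so they are fixed defaults in
  the configuration rather than tuned per run.
* **Deterministic behaviour.** libsvm's decision-value ties resolve by its
  fixed class ordering, which we pin to lexicographic label order via
  factor levels; a training fold containing a single class predicts that
  class.

The grid evaluates feature sets $\{T\}$, $\{\rho\}$, $\{T, \rho\}$ for the
2-class (ET vs control) and 4-class problems with both kernels and reports
the better kernel per cell (ties to linear).

A note on the permutation null used to validate the harness: under full
label permutation the held-out label is exactly the "leftover" of the
training labels, which makes predictions and held-out labels negatively
correlated and depresses LOOCV accuracy a few points below the
marginal-product chance agreement $\sum_c p_\mathrm{true}(c)\,
p_\mathrm{pred}(c)$. Information leakage can only inflate accuracy, so the
suite bounds the permutation mean from above by chance agreement (and by
the majority-class rate) rather than asserting a two-sided match.

## The synthetic cohort generator

No per-subject recordings are distributed with this package, so every
downstream stage is exercised on synthetic sessions from `make_cohort()`.
The generator is first-class, tested code, and its defaults encode the
study conditions it emulates: four groups of 18/6/5/6 subjects; per-site
mean (SD) PSD-ratio targets of 0.55 (0.37) / 2.15 (1.66) / 3.90 (2.59) /
4.74 (1.82) at S1, 0.79 (1.12) / 2.84 (2.42) / 5.16 (5.59) / 6.96 (6.24)
at S2, 0.81 (0.60) / 0.88 (1.14) / 0.97 (0.95) / 2.09 (2.59) at S3; task
times 12.64 (5.53) / 20.53 (14.23) / 19.82 (8.04) / 26.92 (14.95) s; and
ET-group clinical FTM 16.0 (9.2) / 20.4 (3.8) / 36.25 (12.24).

Per subject the generator draws a task-time target and per-site PSD-ratio
targets, a tremor frequency uniform on $[4.5, 11.5]$ Hz (inside the ET band,
away from the band edges so spectral leakage cannot move power across a
boundary), and a latent clinical FTM equal to the severity model evaluated
at the drawn $(T, \rho_{S2})$ plus a Gaussian residual of SD 8.158 FTM
points, clipped to the scale bounds $[0, 144]$. Two blinded-rater scores add
independent N(0, 2.5) rater noise. Signals are then synthesised as:

* **Pen:** an Archimedes spiral $r = a\theta$ traversed at constant angular
  rate over the drawn duration (default 3 turns, 60 mm outer radius,
  100 Hz), with 1-s pen-up lead/trail; the spiral's orientation on the
  tablet is randomised per subject.
* **Voluntary acceleration:** the second finite difference of the pen
  trajectory, low-pass smoothed at 3.5 Hz and mapped into the sensor frame
  by fixed unit vectors, plus a "corrective wobble" — a sum of 12 random
  tones confined to 0.9--3.3 Hz with total SD 0.05 m/s$^2$. The wobble
  represents the sub-movement corrections real drawing always contains and
  supplies the voluntary-band power that the pure constant-rate spiral
  (whose fundamental sits below 0.5 Hz at realistic speeds) would lack.
* **Tremor:** an amplitude-modulated sinusoid (default modulation depth
  0.2 at 0.4 Hz) along a fixed arm axis, plus white sensor noise
  (SD 0.01 m/s$^2$ per axis) and gravity on the z axis.

The tremor amplitude is *calibrated* per subject and site: the
voluntary-only session is synthesised first, its voluntary-band power
$P_\mathrm{low}$ measured through the identical feature path, and the
amplitude set to $A = \sqrt{2\,\rho_\mathrm{target} P_\mathrm{low}}$
(corrected for the gravity-axis projection and the modulation power factor
$1 + d^2/2$). Round-trip accuracy of a few percent is asserted in the
tests.

Two distributional choices depart from the most literal reading of the
summary table and are the package's own:

* **Moment-matched gamma targets.** Several printed cells have SD larger
  than the mean, so a Gaussian would generate impossible negative ratios,
  and a normal truncated at zero would no longer have the printed mean
  (for 0.79 ± 1.12 the truncated mean is about 1.25). Gamma distributions
  with the printed mean and SD keep both moments exactly on a non-negative
  support; an SD of zero degenerates to the mean. Draws go through the
  inverse CDF so a fixed seed yields coupled, monotone draws when a
  configured mean is changed.
* **Per-site targets.** Each site's ratio target is drawn from that site's
  own printed mean ± SD (rather than scaling a single subject-level target
  by fixed per-site gains), reproducing all three sites' distributions
  directly. Within-subject correlation of sites is consequently not
  modelled.

Drawn task times are floored at 5 s so every recording supports the 4-s
Welch segment.

What the generator does **not** emulate: real voluntary drawing spectra
(beyond band location), within-subject correlation across sites, tremor
intermittency beyond sinusoidal AM, sensor dropouts or clock jitter
(a constant pen/IMU offset can be injected, nothing more), rest/postural
conditions, and any biomechanics of the arm. Passing tests therefore show
that the pipeline's operations are correct and self-consistent under the
stated signal model — not that the published dataset-level results (which
depend on undeposited raw recordings) are reproduced.

## Problem sizes and numerical tolerances

The test suite runs entirely on synthetic data built at test time: cohorts
of 10 subjects for pipeline unit tests and the default 35-subject cohort
for end-to-end checks; 20 seeded cohorts for generator fidelity (group
means within two standard errors of the configured means); 500 replicates
of $n = 17$ for OLS coefficient recovery; 200 label permutations for the
classification null; 1000 simulations for nonparametric type-I calibration
(nominal 0.05 ± 0.02); 100 random rotations for orientation invariance at
$10^{-6}$ relative; analytic two-tone ratios at ±5%, which covers Welch
windowing bias at these durations. Full-pipeline reruns with a fixed seed
are asserted byte-identical.

## Known limitations

* The published regression/classification numbers ($r^2$, RMSE, LOOCV
  accuracies, U statistics) characterise a specific undeposited clinical
  sample; this package reproduces the *methods* and the published model's
  worked examples, and validates everything else by construction-based
  properties.
* The vector-magnitude linearisation means injected tremor orthogonal to
  gravity is attenuated in the magnitude; the generator calibrates through
  the same path, so this affects realism, not self-consistency.
* `signal::filtfilt`-style zero-phase filtering is replaced by an internal
  implementation with steady-state edge handling; very short windows
  (< ~0.4 s at the default order) are rejected.
* Pen-up intervals inside the task are included in the accelerometer
  segment (the window is first-to-last pen-down); whether the original
  analysis excluded them is unstated. The stroke labeller can report the
  intervals if a different convention is wanted.
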