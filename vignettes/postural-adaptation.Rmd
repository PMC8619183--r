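---
title: "Methods: from perturbation recordings to a discriminant model of postural adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from perturbation recordings to a discriminant model of postural adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`posturadapt` implements an analysis chain for studies in which older
adults stand on a movable platform that delivers a repeated, identical
surface perturbation (anterior translation followed by a toes-down tilt),
and the question is which sensory, motor, psychological and postural-control
variables distinguish the subjects who learn to manage the perturbation from
those who fall every time. This vignette documents the modelling choices:
what each stage computes, which conventions were open and how they were
fixed, and what the synthetic cohort generator does and does not emulate.

## Study structure

Each subject contributes:

* three perturbation trials with synchronized joint angles (200 Hz) and
  bilateral tibialis anterior / medial gastrocnemius EMG (3000 Hz);
* four 30 s quiet-stance trials (stable/unstable surface crossed with eyes
  open/closed) recorded as centre-of-pressure (COP) traces at 3000 Hz;
* a battery of scalar measures: demographics, medication count, six
  fall-related-concern items, cognitive screening, visual acuity, four
  joint-position-sense errors, six maximal isometric torques, a five-trial
  reaction-time test and the Short Physical Performance Battery (SPPB).

A subject who steps or loads the safety harness in a trial has fallen in
that trial. Group membership hinges on the **third** trial only
(`classify_faller()`): failing it makes a subject a Faller; anyone who
manages it in place is a Non-faller, whatever happened earlier. This
encodes the adaptation question — the third exposure is no longer novel.

## Kinematic features

Joint angles (ankle, knee, hip bilaterally; one back angle) are expressed
relative to each subject's quiet-stance posture (`normalize_to_quiet_stance()`),
with flexion of back/hip/knee and ankle plantar flexion positive. Left and
right are averaged pointwise.

* **Feedforward posture** — the mean angle over the 100 ms before platform
  onset. The window is half-open, `[onset − 100 ms, onset)`: the onset
  sample belongs to the response, not to the anticipation, and at 200 Hz
  the window holds exactly 20 samples. A statement like "the window
  −100–0 ms" does not fix the endpoints; this convention does.
* **Feedback range** — per joint, the maximum flexion excursion and the
  maximum extension excursion between platform onset and the halt of the
  platform in its most anterior, tilted pose. Both are floored at zero, so
  a joint that never crosses neutral in one direction scores 0 for that
  direction rather than a negative value. Feedback angles use the same
  single quiet-stance reference as the feedforward window (not a per-trial
  re-baseline): one reference keeps feedforward and feedback features on
  the same scale.

When platform timing is not provided by the hardware,
`detect_platform_onset()` recovers onset as the first time translation
velocity exceeds 0.5 cm/s sustained for 50 ms.

## EMG processing

`preprocess_emg()` reduces each channel with the standard surface-EMG
chain: 20–500 Hz band-pass, 50 ms centred sliding-window RMS, division by
the muscle's maximal-voluntary-contraction (MVC) reference, then pointwise
left/right averaging into one tibialis and one gastrocnemius envelope.
Conventions that had to be fixed:

* **Filter.** Zero-phase (forward–backward) Butterworth. Two passes square
  the magnitude response, so the design corners are pre-shifted (in the
  prewarped analog domain) to land the *two-pass* response at −3 dB at 20
  and 500 Hz. The analysis filter uses order 8 per pass: steep enough that
  a 600 Hz component is rejected by more than 20 dB while the corners stay
  at −3 dB — a 4th-order double-pass cannot deliver both. The 10 Hz COP
  low-pass keeps order 4, where these requirements are easily met.
* **RMS window.** 50 ms, centred, truncated at the record edges; the
  window length is rounded to an odd sample count so the centre is exact.
* **MVC reduction.** The MVC reference is the maximum of the RMS envelope
  of the MVC trial (a scalar per muscle, in mV). Envelopes are therefore
  in fraction-of-MVC.

**Co-contraction index.** Per sample,
`CCI(t) = (lower(t) / higher(t)) · (lower(t) + higher(t))`, where lower and
higher are the smaller and larger of the two envelopes, and `CCI = 0`
where both are silent — the standard ratio-times-sum index of simultaneous
agonist–antagonist activation. It is symmetric, scale-equivariant
(`CCI(αa, αb) = α·CCI(a, b)`), equals twice the common level under exactly
matched activation, and is bounded by twice the larger envelope. The
feedforward CCI averages over the same half-open 100 ms pre-onset window
as the kinematics; the feedback CCI averages from the tibialis anterior
onset to the platform halt.

**Onset detection.** Visual onset marking is not reproducible, so
`detect_muscle_onset()` uses a threshold rule: the earliest post-onset time
at which the envelope exceeds the baseline mean plus `k = 3` baseline
standard deviations continuously for at least 25 ms. Both `k` and the
sustain are arguments. If no onset is found (or it falls after the halt)
the feedback CCI is reported missing while the feedforward CCI is kept.

## Sway ellipse

COP traces are low-pass filtered at 10 Hz (zero-phase) and mean-centred
— no detrending, since a mean-reverting quiet-stance trace has no trend to
remove. The "smallest ellipse fitting 95% of the swarm" is implemented as
the PCA prediction ellipse: eigendecompose the 2×2 sample covariance and
take the ellipse with semi-axes `sqrt(χ²(0.95, 2) · λᵢ)` along the
eigenvectors, with area

> area = π · χ²(0.95, 2) · sqrt(λ₁ · λ₂).

This is the estimator the PCA phrasing describes; a literal minimum-area
covering ellipse is a different (combinatorial) object and is out of scope.
For large Gaussian swarms the ellipse encloses 95% of the points by
construction; `sway_ellipse()` reports the realised enclosed fraction.
Collinear or constant swarms return area 0 with a degenerate flag. Stance
standardization (75% of inter-ASIS distance) is metadata and does not
enter any computation.

## Multivariate modelling

* **Scaling.** Unit-variance scaling with mean-centring (`scale_uv()`),
  computed ignoring missing cells; zero-variance columns cannot be scaled
  and are dropped with a warning.
* **PCA.** `fit_pca_nipals()` uses NIPALS, which tolerates missing values
  by restricting projection sums to observed cells. Components deflate
  sequentially; loadings are unit norm; the sign is fixed so the
  largest-magnitude loading is positive (scores then correlate positively
  with their dominant variable, making coefficient directions
  reproducible). NIPALS converges linearly at the ratio of the leading
  eigenvalues, so the defaults allow many cheap iterations
  (`tol = 1e-8`, `max_iter = 5000`) and non-convergence is an error, not a
  silent result. PCA Q2 is estimated by element-wise deletion: cells are
  assigned to 7 diagonal folds, each fold is set missing in turn, the
  model is refit and the deleted cells predicted; `Q2 = 1 − PRESS/SS`.
* **Base models.** Four constructs — six fall-concern items, four sway
  areas, six height-normalized torques, four joint-position-sense errors —
  are each collapsed to a one-component PCA score (`fit_base_models()`);
  the score joins the top-model table and the constituents leave it. We
  report the explained variance of these PCA models as R2(X): a PCA
  explains predictor variance, even when discriminant-analysis software
  labels the quantity R2Y.
* **OPLS-DA.** The top model encodes the class as 0/1 with Faller = 1,
  removes `n_orth = 1` component of predictor variation orthogonal to the
  class, and fits one predictive PLS component on the filtered matrix
  (`fit_oplsda()`). With `n_orth = 0` the model reduces exactly to
  one-component PLS1 (tested against an independent reference
  implementation). Regression coefficients are composed back onto the
  original scaled variables, so `ŷ = ȳ + X·b` reproduces the fitted
  values; positive coefficients mean higher values in Fallers. Remaining
  missing cells are imputed at the column mean (zero after scaling).
* **Cross-validation.** `Q2 = 1 − PRESS/SS` over 7 folds assigned
  deterministically round-robin over sorted subject ids. If that
  assignment would leave a training split with a single class (possible
  when all five Fallers share a fold), assignment falls back to the same
  round-robin within each class — still deterministic. The top-model
  roster is every scalar not inside a construct plus the trial-1/trial-3
  kinematic and CCI features plus the four construct scores.
* **Coefficient significance.** Jackknife over the CV segments: refit
  excluding each fold, and convert the spread of per-segment coefficients
  into `SE = sqrt((G−1)/G · Σ(b_g − b̄)²)`; the 95% CI is
  `b ± t(0.975, G−1)·SE` centred on the full-model coefficient, and a
  variable is significant iff the CI excludes zero.
* **Permutation validation.** Labels are permuted `n_perms = 200` times
  (seeded); each permuted model contributes (|corr with original labels|,
  R2Y, Q2). Straight lines through these points (original model included
  at corr = 1) give intercepts at corr = 0; the model is judged *weak* if
  the Q2 intercept exceeds 0.05 or ≥5% of permuted models reach the
  original Q2, else *strong*.
* **Univariate companion.** Mann–Whitney U per continuous variable (exact
  for group sizes ≤25 without ties, normal approximation with tie
  correction otherwise; identical pooled values return p = 1), Fisher's
  exact test for sex, and within-group paired Wilcoxon signed-rank tests
  for every trial-1/trial-3 feature pair. No multiple-testing adjustment
  is applied, and the report says so.

## The synthetic cohort generator

No public dataset accompanies this design, so `simulate_cohort()` /
`simulate_cohort_features()` generate cohorts with the statistical
structure the analysis assumes. Defaults describe a 35-subject cohort with
exactly `round(35 · 5/35) = 5` Fallers.

* **Scalars.** Group means follow published descriptive medians for this
  population (Fallers: older, shorter, more medications, weaker knee
  extension and ankle plantar flexion, slower reaction time, lower SPPB,
  larger sway); sds are set from the interquartile ranges (IQR/1.35).
  Instrument ranges are respected (Likert 1–4, FES-I 16–64, MMT 0–30,
  SPPB 0–12). Variables of the same construct share a latent factor with
  correlation 0.6 — similar-construct items co-vary within a person, which
  is exactly what makes a one-component base model meaningful.
* **Trials.** The platform profile is 8 cm anterior translation at
  10 cm/s, then a 6° tilt at 11°/s, tilted back at the same rate; phases
  are strictly sequential. Non-fallers progressively adopt a flexed
  anticipatory posture by trial 3 while relaxing tonic co-contraction;
  Fallers mainly increase ankle plantar flexion and ramp co-contraction up
  (multipliers 1.2/1.5/1.8 across trials). Reactive excursions follow the
  published feedback range-of-motion pattern, including the Fallers' large
  trial-1 back-extension response. EMG is a 20–450 Hz band-limited
  Gaussian carrier amplitude-modulated by tonic-plus-burst envelopes; the
  tibialis burst starts 120 ms after onset (a physiologic medium-latency
  response; exact latencies are not reported for this protocol).
* **Sway.** AP/ML excursions are independent Ornstein–Uhlenbeck processes
  (mean-reverting, rate 1 s⁻¹), so 30 s traces have a finite stationary
  ellipse — a random walk would not. Stationary sds per group × condition
  are back-calculated from published median ellipse areas via the area
  formula above, and a subject-level lognormal magnitude factor
  (log-sd 0.25, about ±50%) correlates a subject's four areas.
* **Outcomes.** Fallers fall in all three trials; Non-fallers always
  manage trial 3 and may fall earlier (30%/10% in trials 1/2).
* **Missingness** is optional missing-at-random per scalar variable,
  default 0.

**What the generator does not emulate:** marker-level kinematics (angles
are generated directly; no inverse kinematics), realistic EMG spectra and
artefacts, non-stationary sway, learning *within* a trial, recruitment and
attrition arithmetic, or correlations between constructs beyond those the
group effects induce. Passing tests on these cohorts therefore demonstrate
that the pipeline recovers known structure of the kinds listed — not that
it would behave identically on real recordings.

## Calibration and problem sizes

The test-suite experiments use sizes chosen to give stable Monte-Carlo
estimates at desk scale:

* Ellipse closed-form and coverage checks: 10⁵ points for the 1% area
  comparison; 100 trials × 3000 points for the mean enclosed fraction.
* Q2 null behaviour: 50 seeded pure-noise cohorts (n = 35), mean Q2 ≤ 0.05.
* Significance-rule calibration: 100 cohorts of n = 35 with both classes
  well represented (17/18), one variable with a 2 sd standardized effect
  and nine null variables. The jackknife CI flags the effect variable in
  ≥90% of cohorts and null variables at roughly the nominal 5%. At the
  study's own 5/30 imbalance the same rule keeps its type-I behaviour but
  its power drops to about 70%: leaving out a fold removes a large share
  of the five positives and inflates the jackknife SE. That is a real
  limitation of jackknifed discriminant coefficients in very unbalanced
  samples, and a reason such models warrant permutation validation.
* Direction recovery: 12 independently seeded default cohorts, run through
  the full feature–scale–base-model–significance chain; in each, every
  flagged coefficient among the generated effect directions must carry the
  generating sign.

## Known limitations

* The OPLS-DA coefficient CIs are conditional on the chosen fold layout;
  a different deterministic assignment gives slightly different CIs.
* PCA Q2 by element deletion can be strongly negative for weakly
  structured matrices when a loading concentrates on one variable — a
  known hazard of the estimator, reported as-is rather than floored.
* With five subjects in one class, leave-fold-out statistics are noisy;
  permutation validation is the more trustworthy generalisability check,
  which is why `run_pipeline()` always includes it.
* The generator's effect directions and magnitudes are stand-ins for one
  published cohort; they are configuration, not estimates, and every entry
  can be overridden through `cohort_config()`.
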