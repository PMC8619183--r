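# posturadapt

Why do some older adults fail to adapt to a surface perturbation they have
already experienced twice? `posturadapt` is an R implementation of the full
analysis chain for repeated-perturbation balance studies: it turns raw
laboratory recordings — joint-angle time series, bilateral surface EMG,
force-plate centre-of-pressure (COP) traces and a battery of subject-level
tests — into interpretable features of feedforward and feedback postural
control, and models which of those features separate the subjects who fall
in every trial ("Fallers") from those who manage at least the final trial
("Non-fallers").

It is written for movement-science and biostatistics researchers who want a
scriptable, reproducible alternative to point-and-click chemometrics
software for this class of small-cohort discriminant problems.

## What it computes

**Features per subject**

* *Feedforward posture*: mean joint angles (ankle, knee, hip, back;
  flexion/plantar-flexion positive, quiet stance = 0°) over the half-open
  100 ms window before platform onset.
* *Feedback range*: maximum flexion and extension excursion per joint from
  platform onset to the platform halt, floored at 0.
* *Co-contraction index* between tibialis anterior and gastrocnemius
  envelopes (20–500 Hz zero-phase band-pass, 50 ms RMS, MVC-normalized,
  sides averaged):

  CCI(t) = (lower(t) / higher(t)) · (lower(t) + higher(t)),

  averaged over the feedforward window and over the period from tibialis
  onset to platform halt.
* *Sway area*: the 95% PCA prediction ellipse of the low-pass-filtered COP
  swarm, area = π · χ²(0.95, 2) · √(λ₁λ₂) from the eigenvalues of the 2×2
  covariance, for four quiet-stance conditions.

**Models**

* Hierarchical PCA base models (NIPALS, missing-value tolerant) collapse
  the fall-concern, balance, strength and joint-position-sense constructs
  into one score each.
* An OPLS-DA top model (one predictive + one orthogonal component,
  Faller = 1) with training R2Y and 7-fold cross-validated
  Q2 = 1 − PRESS/SS.
* Jackknife-over-folds confidence intervals per coefficient; a variable is
  significant iff its CI excludes zero.
* Permutation validation: 200 label permutations, R2Y/Q2 regression
  intercepts and a strong/weak verdict.
* Univariate companions: Mann–Whitney U, Fisher's exact test for sex, and
  paired Wilcoxon signed-rank tests for trial-1 vs trial-3 features.

Because no public dataset accompanies this design, the package ships a
seeded synthetic-cohort generator (`cohort_config()`, `simulate_cohort()`)
that emulates the study's structure — 35 subjects with exactly 5 Fallers,
three perturbation trials with trial-dependent feedforward adaptation in
Non-fallers only, EMG stiffening in Fallers, and four sway conditions with
group- and condition-dependent magnitude — so every stage is testable end
to end.

## Worked example

```r
library(posturadapt)

config <- list(
  cohort     = cohort_config(seed = 1),   # the default synthetic study
  constructs = default_constructs(),
  model      = list(n_perms = 200)
)
report <- run_pipeline(config)
print(report)
#> Postural adaptation analysis report
#>   35 subjects ( 5 Fallers / 30 Non-fallers )
#>   base model fall_concerns  R2(X) = 62.3%  Q2 = 42.4%
#>   base model balance        R2(X) = 92.3%  Q2 = 84.2%
#>   base model strength       R2(X) = 67.4%  Q2 = 51.3%
#>   base model jps            R2(X) = 68.6%  Q2 = 41.6%
#>   top model OPLS-DA: R2Y = 96.8%, Q2 = 95.0%
#>   significant coefficients: 23 of 41
#>   permutation verdict: strong
```

Each base model compresses one construct into a single component: R2(X) is
the fraction of that construct's variance the component explains and Q2 its
cross-validated counterpart. The top model's R2Y is the fraction of class
variance explained in training and Q2 the 7-fold cross-validated predictive
ability; the permutation verdict says whether that Q2 collapses once the
class labels are scrambled (here it does not: the synthetic default cohort
is a deliberately strong-signal dataset).

Coefficients with jackknife CIs excluding zero carry the group contrast.
On the run above the largest include (positive = higher in Fallers):

```r
dplyr::filter(tidy(report), significant)
#>   cci_feedback_t3      +0.029    trial-3 co-contraction (stiffening)
#>   cci_feedforward_t3   +0.027    anticipatory stiffening before trial 3
#>   ff_ankle_t3          +0.014    more plantar flexion before trial 3
#>   ff_knee_t3 / ff_hip_t3  −      Fallers miss the flexed anticipatory posture
#>   score_strength       −0.023    lower leg strength
#>   reaction_time        +0.015    slower reaction time
#>   ...
```

`autoplot(report$coefficients)` draws the coefficient chart,
`autoplot(report$permutation)` the permutation plot, and
`write_report(report, "out/")` exports all tables as CSV/JSON with a
manifest. Individual stages are ordinary data-frame-in/tibble-out
functions (`preprocess_emg()`, `sway_ellipse()`, `fit_oplsda()`, ...) and
chain with the pipe.

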