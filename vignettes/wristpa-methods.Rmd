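---
title: "Methods: wrist-accelerometry activity recognition and energy expenditure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wrist-accelerometry activity recognition and energy expenditure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristpa)
```

## The problem

Wrist-worn tri-axial accelerometers record acceleration in g at 30--100 Hz
while a person goes about scripted daily activities; a portable indirect
calorimeter measures oxygen uptake at the same time. From these two streams
one wants to recover, window by window, the hallmark measures of physical
activity: the **type** of activity (sedentary, locomotion, lifestyle), its
**intensity** (low, light, moderate, from the metabolic cost), the
**individual activity** itself (out of 33 scripted household and exercise
tasks), and the **energy expenditure** in metabolic equivalents (METs,
where 1 MET is resting metabolism and MET = VO~2~ / 3.5 mL·min^−1^·kg^−1^).
Performance must be estimated without letting any participant contribute to
both sides of a train/test split, and separately for young (20--50 y),
middle-aged ((50--70] y) and older ((70--89] y) adults, because wrist
movement patterns change with age.

`wristpa` implements this pipeline end to end: ingestion and cohort
accounting, windowing and feature extraction, label derivation, four
learner families behind one contract, participant-grouped nested
cross-validation, and an experiment runner that reproduces the full
116-model grid. A synthetic-cohort generator supplies labelled signals with
the statistical structure the analysis assumes, so every stage runs and can
be validated without access to laboratory recordings.

## Windowing and features

Recordings stay at their native sampling rate (30, 80 or 100 Hz; the rate
is validated against the observed median sample spacing with a 1%
tolerance) — **no resampling is ever performed**, since a 60-s window
carries ample resolution at any of the three rates. Each labelled activity
interval is cut into consecutive non-overlapping 60-s windows anchored at
the interval start; trailing partial data are discarded, so an interval of
length L yields ⌊L/60⌋ windows and a window always spans exactly
`round(60 * rate_hz)` samples of a single activity.

Per window, 49 features are computed in a fixed canonical order
(`wpa_feature_names()`). With the per-sample vector magnitude
VM = √(x² + y² + z²) and the arm angle a = asin(x / VM) · 180/π:

* **Time domain (46):** mean and SD of VM and of the angle; per-axis mean,
  SD and coefficient of variation (100 · SD/|mean|); min, max, 25% and 75%
  quantiles, third and fourth central moments, skewness and kurtosis of VM
  and of each axis; and the CV of VM.
* **Frequency domain (3):** from the DFT modulus of the VM series with the
  DC bin excluded, `p625` — the fraction of total modulus in the
  0.6--2.5 Hz human-movement band; `df` — the frequency of the largest
  modulus; `fpdf` — that bin's share of the total.

Several conventions had to be fixed where common usage varies; the package
freezes these choices for reproducibility:

* SDs use the n−1 sample estimator; quantiles interpolate linearly between
  order statistics (the dominant defaults in scientific software).
* Third and fourth moments are **central** moments; skewness and kurtosis
  are m₃/m₂^1.5 and m₄/m₂² with population central moments (non-excess
  kurtosis). A constant signal has m₂ = 0; the guard emits 0 for both.
* Coefficients of variation divide by |mean| and emit 0 when
  |mean| < 10⁻⁶ g: per-axis means cross zero routinely and an unbounded CV
  would poison the feature table. Samples with VM = 0 contribute a 0°
  angle; the x/VM ratio is clamped to [−1, 1] against rounding.
* The DC bin is excluded from all three spectral features (it encodes
  gravity, not movement); the 0.6 and 2.5 Hz band edges are inclusive; tied
  spectral maxima resolve to the lowest frequency; a numerically zero
  spectrum (constant VM) yields (0, 0, 0).

Every time feature is cross-checked in the test suite against an
independent brute-force implementation on 1000 random windows at a 10⁻⁹
relative tolerance, and the spectral features against a naive
O(n²) discrete Fourier transform on bin-aligned tones.

## Labels

Breath-by-breath VO~2~ is smoothed with a **centered 30-s running
average** (partial windows at the edges), averaged over a user-supplied
steady-state sub-interval — plateau identification is expert judgement this
package deliberately does not automate — and divided by 3.5 to give METs.

Intensity cutoffs are configuration with conventional defaults:
low ≤ 1.5 METs < light ≤ 3.0 METs < moderate, upper bounds inclusive.
The activity-to-type mapping likewise ships as an editable named vector:
walking and stair tasks → locomotion; television, computer work and
standing still → sedentary; household chores → lifestyle; the three
resistance exercises and stretching yoga → `"none"` and are dropped from
type recognition (29 of 33 activities remain). Both defaults are stated
assumptions of this package, not measured assignments.

Age groups use the study brackets: young = [20, 50], middle = (50, 70],
old = (70, 89]; the `"all"` stratum pools the three groups and its models
are trained on the pooled data (not ensembles of the group models), which
keeps the stratum a first-class model like the others.

## Learners, weights and tuning

Four families sit behind one fit/predict contract (`wpa_fit()`): CART
decision trees (`rpart`), random forests (`ranger`), gradient boosting
(`xgboost`) and the lasso (`glmnet`; L1-logistic for classification, L1
linear regression for METs). Class imbalance — a one-vs-rest sedentary task
is roughly 1:9 — is countered by inverse-frequency class weights
w~c~ = N/(K·N~c~), passed to every backend as per-row sample weights so the
mechanism is uniform across families. Classification models expose
class-probability scores for AUC; all fits are deterministic given the
spec seed (single-threaded backends, seeded RNG).

Feature importance is impurity-based for the tree families and the
normalized absolute coefficients for the lasso, always rescaled to sum to
one over the 49 features.

Hyperparameter grids are not prescribed by the study design, so the
package ships small conventional ones (`default_grids()`): tree depth
{3, 5, 10, 30}; forest size {100, 300} × features-per-split {7, 16};
boosting depth {3, 6} × learning rate {0.1, 0.3} × rounds {100, 300}; a
50-point logarithmic lasso penalty grid expressed as fractions of the
data-derived maximal penalty (so the grid transfers across datasets).
`reduced_grids()` fixes one setting per family; with a single candidate
the inner tuning loop is skipped exactly, which is how a full 116-model
run stays desk-scale.

## Nested cross-validation

Participants — never windows — are randomly assigned to 5 size-balanced
outer folds. For each outer fold, the remaining participants are split
into 4 inner folds; every grid setting is fit on each inner-training set
(class weights recomputed there) and scored on the inner validation fold.
The selection metric is positive-class F1 for binary tasks, macro F1 for
the 33-class task and negative RMSE for regression — the study design
names no inner metric, so these are frozen package choices consistent
with how the outer results are reported. The best setting is refit on the
full outer-training set and evaluated once on the held-out fold.

Reported results are the mean and SD over the 5 outer folds, plus the
confusion matrix summed over folds and the fold-averaged importance
ranking. Separately, the setting with the best mean inner score is refit
on all data and kept as `final_model` — reconciling "report fold
mean ± SD" with "the best model was chosen" in one object. A metric that
is undefined on some fold (a class absent from the outer test fold) is
recorded as missing, excluded from the mean and flagged with a warning,
never imputed. Participant-disjointness of every outer split is asserted
on every run; a violation is a hard error, not a warning.

## The experiment grid

`experiment_grid()` enumerates the full study structure: 3 type targets ×
4 learners × 4 strata (48 models), 3 intensity targets × 4 × 4 (48), one
regression per learner and stratum (16), and the 33-class task with the
gradient-boosting learner only, per stratum (4) — 116 model instances.
The counts are structural: they do not depend on cohort size or seed.
`run_experiment_grid()` runs nested CV per cell, records skipped cells
(e.g. an empty stratum) with warnings rather than aborting, and
`report_tables()` renders the standard shapes: per-target F1 tables by
stratum, the RMSE table, the 33-row individual-activity table with a
macro-average row, top-15 importance tables and confusion matrices — every
cell a mean (SD) over exactly the 5 outer folds of one CV result.

## The synthetic cohort generator

Real recordings of this kind are not freely available, so the generator
emulates the statistical structure the pipeline relies on. Each activity
profile is: a static gravity orientation (unit 3-vector), one sinusoid per
axis at the activity's dominant frequency with per-axis amplitude and a
random phase per interval (windows within an activity are exchangeable but
not identical), plus i.i.d. Gaussian noise (default SD 0.01 g). The default
catalog ships 33 profiles named as the scripted activities, with distinct
(frequency, amplitude, orientation) combinations per activity — sedentary
below 0.3 Hz at millig amplitudes, locomotion at 1.4--2.4 Hz and 0.25--0.55 g,
lifestyle in between — so type classes are well separated and individual
activities are distinguishable.

MET labels are drawn per interval from Normal(met_mean, met_sd), truncated
below at 0.1 MET (energy expenditure cannot be non-positive). The default
means are plausible values for each task — configuration, not measured
ground truth — placed at least four SDs inside one default intensity class
so drawn labels stay consistent with the configured class. Ages are drawn
uniformly within each group's bracket; a fixed seed makes the whole cohort
byte-identical across runs.

What the generator does **not** emulate is equally important for reading
the validation results: no gait harmonics, autocorrelated or heteroscedastic
noise, device-orientation drift, non-wear, transitions within an interval,
or between-participant movement idiosyncrasies. Passing tests therefore
demonstrate that the pipeline's plumbing, leakage control and estimators
behave correctly on data with known structure — near-perfect synthetic F1
values say nothing about accuracy on laboratory recordings, where
between-participant variability dominates.

## Validation problem sizes

The test suite and the acceptance script validate at deliberately modest
sizes chosen as the package's own desk-scale defaults: a 15-participant
cohort (5 per age group, the minimum allowing 5 participant-grouped outer
folds per stratum), 120 s per activity at 30 Hz (two windows per interval,
990 windows in all), and `reduced_grids()` for full-grid runs. Recovery
checks use: type-classification macro F1 ≥ 0.9 on the separable cohort;
MET regression RMSE within [0.2, 0.45] when label noise has SD 0.25 METs
(an estimator cannot beat the noise floor and should approach it); and a
mean AUC inside [0.35, 0.65] after permuting labels within participants
(chance behaviour under the null). Enrollment accounting (264 → 253
included, 247 calorimetry-eligible, 941 visits) is validated on a roster
fixture constructed from the printed exclusion and attendance counts.

## Known limitations

* The activity→type mapping, intensity cutoffs and per-activity MET levels
  are editable defaults, not study-measured values.
* Steady-state plateau selection is manual by design; `steady_state_met()`
  only averages a supplied sub-interval.
* No vigorous-intensity class is modelled, and no repeated CV or formal
  tests comparing learners across age strata are provided.
* The raw-file reader handles the canonical CSV dialect (plus ISO-8601
  timestamps), not proprietary binary device archives.
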