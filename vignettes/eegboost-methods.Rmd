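---
title: "Predicting per-symptom antidepressant response from quantitative EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting per-symptom antidepressant response from quantitative EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegboost)
```

## The problem

Depression trials usually summarise outcome as a change in a total severity
score, yet individual symptoms (sleep disturbance, psychomotor retardation,
loss of insight, ...) respond at different rates and may have distinct
neural correlates.  `eegboost` implements a per-symptom prediction pipeline:
for each of the 21 items of the Hamilton Rating Scale for Depression
(HRSD-21), it predicts the *improvement* — the week-8 item score minus the
baseline item score, negative meaning the symptom improved — from
pretreatment eyes-closed resting-state EEG band-power features together
with the baseline item scores, using gradient-boosted decision trees
(GBDTs).  Discrimination is summarised by the concordance (C) index,
feature influence by Shapley attributions, and the incremental value of the
EEG over the symptom scores alone by a paired C-index difference.

Ten HRSD items are rated 0–4 and eleven are rated 0–2
(`hrsd_items()`); improvements are therefore small signed integers.
Because the clinical cohort that motivates this design is not public, the
package ships a first-class synthetic cohort generator with planted,
configurable band-power → symptom-improvement effects, so every stage of
the pipeline is exercised end-to-end by code alone.

## Spectral features

Recordings are 26-site (10-20/10-10 montage, `eeg_montage()`), eyes-closed,
nominally 2-minute signals in microvolts.  Features are built from the
Welch spectral density: successive windows (default 2 s, the shortest
window resolving the 0.5 Hz lower delta edge) with 50% overlap, per-window
mean removal (so DC offsets cannot leak into delta), a Hanning taper, and
averaging of the windowed periodograms.  The density is normalised so its
integral approximates the signal variance.

Absolute band power is the Simpson-rule integral of the density over each
canonical band — delta 0.5–4, theta 4–8, alpha 8–12, beta 12–30, gamma
30–100 Hz — restricted to the available frequency bins; relative power
divides each band by the sum of the five (so relative powers sum to one —
the common quantitative-EEG convention; the denominator choice is not
dictated by the method itself and is logged here as an assumption).  Two
derived features follow the field's conventions: frontal alpha asymmetry,
alpha power at F4 minus the homologous left site F3, and a per-site
beta–alpha ratio.  Site labels pass through the legacy alias map
(T3/T4/T5/T6 ≡ T7/T8/P7/P8).

### A numerical subtlety: Simpson quadrature on spectral lines

Composite Simpson weights alternate 4/3 and 2/3 across interior bins.  A
Hanning-windowed sinusoid that falls exactly on a bin occupies three bins
with power ratio 1:4:1, and its integral under those alternating weights is
off by ±11% depending on the parity of the peak bin — far outside the ~2%
accuracy one expects for a pure tone of amplitude $A$ with analytic power
$A^2/2$.  `welch_psd()` therefore evaluates the density on a two-fold
zero-padded frequency grid.  Zero padding does not change the integrated
power (the normalisation is independent of the transform length) but
samples the window's main lobe smoothly, after which Simpson integration of
a pure 10 Hz tone recovers $A^2/2$ to within about $10^{-5}$ relative
error.  Simpson remains the quadrature; the padded grid is a numerical
choice.  When the number of bins in a band is even, the final panel is
closed with a trapezoid; for the zero-alpha corner case the beta–alpha
ratio emits a large finite sentinel (`1e12`) with a warning rather than
failing a whole cohort, which is harmless for tree models because the
sentinel is monotone.

## The model search

For one symptom, the training procedure searches the cross of

* **feature combinations** — absolute *or* relative power × every nonempty
  subset of the five bands × a region filter (all 26 sites; frontal
  F7/F3/Fz/F4/F8; occipital O1/Oz/O2; or both), 2 × 31 × 4 = 248
  combinations in the full space, enumerated deterministically
  (`enumerate_feature_combinations()`), optionally extended with the
  asymmetry and ratio features; and
* **tree parameters** — number of estimators, maximum depth and maximum
  leaf count for a squared-error GBDT.  The published account names these
  grid axes but not their values; the default grid is
  `n_estimators ∈ {50, 100, 200}`, `max_depth ∈ {3, 5, 7}`,
  `num_leaves ∈ {7, 31}` (rows violating `num_leaves ≤ 2^max_depth` are
  dropped) with the learning rate fixed at 0.1.

Every pair is scored by the pooled C index of stratified 5-fold
out-of-fold predictions: folds are near-equal in size (±1) and spread each
outcome class across folds in near-proportional counts.  For this
integer-valued outcome a "class" is a distinct improvement value; classes
with fewer members than folds are merged into the nearest-valued class.
Each subject's prediction always comes from the model that never saw it,
and predictions are pooled in subject order.  The maximising pair wins;
ties resolve to the earlier enumeration entry, so the search is fully
deterministic given its seeds.

In the default `eeg_hrsd` mode the 21 baseline item scores are always
appended to the EEG features; `hrsd` mode uses the baseline scores alone
(the combination axis collapses); `include_treatment` adds three binary
arm indicators (escitalopram / sertraline / venlafaxine-XR).

**Selection optimism.**  Model selection and the reported pooled C index
share the same cross-validation — there is no outer loop — mirroring the
single-level procedure this pipeline reproduces.  The winner's C index is
therefore optimistically biased, most visibly near chance level where the
maximum over a search space of null models sits above 0.5.  A nested mode
(`nested = TRUE`) that selects hyperparameters inside each training fold is
provided for users who want an honest point estimate; the null-calibration
check below evaluates the selected configuration on a *fresh* permutation
for the same reason.

## Evaluation

* **C index** (`c_index()`): over all usable pairs (unequal outcomes), the
  fraction ranked concordantly; tied predictions earn half credit, the
  standard generalisation — so constant predictions score exactly 0.5.  The
  pair count is implemented in C++ and tested against an exhaustive R
  double loop and the `survival` package's estimator.
* **Uncertainty**: percentile intervals from a nonparametric bootstrap
  (default 1000 replicates) over paired (prediction, outcome) resamples of
  the pooled cohort.  Resamples with constant outcomes are skipped and
  counted; more than 50% degenerate resamples aborts.  The percentile
  interval is the default as the simplest defensible reading of
  "nonparametric bootstrap"; bias-corrected accelerated intervals are
  available via `bootstrap_ci(..., type = "bca")`.
* **ΔC** (`delta_c_index()`): the increment of the EEG + HRSD model over
  the HRSD-only model, with a *paired* bootstrap (the same resample indices
  applied to both prediction vectors) — the variance-correct choice for two
  models evaluated on the same subjects; "significant" means the interval
  excludes zero.
* **Calibration** (`calibrate()`): a univariate lasso
  ($\tfrac{1}{2n}\sum(y - b_0 - b_1 x)^2 + \lambda |b_1|$, default
  $\lambda = 0.01$, closed-form soft-thresholding solution) maps raw
  predictions to the outcome scale; `fit_metrics()` then reports $R^2$,
  MAE, and the calibration slope and intercept.  The method description
  this follows conflates "square regularization loss" with the lasso
  acronym; the implemented penalty is the named method (L1), and $\lambda$
  is exposed so either reading can be reproduced.

## Feature importance

`tree_shap()` returns exact per-subject Shapley attributions under the
tree-conditional-expectation convention (computed by the tree library's
TreeSHAP path; validated in the test suite against a brute-force
subset-enumeration oracle over the parsed trees, and for local accuracy —
base value plus attributions equals the prediction — on every subject).
`aggregate_importance()` converts attributions to percentages of the mean
*absolute* attribution: a signed mean can cancel to zero, which would make
positive percentage contributions meaningless, so the absolute-value
reading is the only consistent one.  By default attributions are computed
by applying each fold's model to its own validation fold and pooling
(`model_importance(..., refit = "pooled")`), matching the pooled-prediction
philosophy; `refit = "all"` attributes under a single model refitted to the
full cohort.  Which data the original analysis attributed is not stated;
the pooled choice avoids attributing a model to subjects it memorised.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions end to end:

* **EEG**: 26 sites, 250 Hz, nominally 120 s eyes-closed.  Each channel is
  a sum over bands of band-limited Gaussian noise synthesised in the
  frequency domain, so the expected band power equals the squared profile
  amplitude (µV²).  The default amplitude profile has posterior-dominant
  alpha (occipital ×1.8, parietal ×1.4), strong slow activity and weak
  fast activity.  Between-subject variability is a per-subject, per-band
  lognormal modifier (log-SD 0.35) times a per-site lognormal jitter
  (log-SD 0.2); the source data's subject-level variance structure is
  unpublished, so this two-level scheme is the package's own documented
  stand-in.  Bands that cross the configured Nyquist edge are truncated
  with a message (at the 250 Hz default the full 30–100 Hz gamma band is
  representable).
* **Scores**: baselines are discretised truncated normals centred at 60%
  of each item's scale (SD 30%); improvements follow
  $\text{round}(\beta_0 + \beta_1 b + \beta_2 z(f) + \varepsilon)$, with
  $z(f)$ the within-cohort standardised value of a named EEG feature and
  $\varepsilon \sim N(0, \sigma)$, clipped so week-8 scores stay on scale
  (a configuration that clips more than half its improvements warns).  The
  pre-clipping values are retained for exact arithmetic checks.
* **Planted truth**: by default one effect — occipital alpha power
  (`"Oz alpha absolute"`) drives improvement in item 1 — with
  $\beta_0 = 0.32$, $\beta_1 = -0.52$, $\beta_2 = -1.0$, $\sigma = 0.97$.
  These coefficients were calibrated once, by simulation over independent
  seeds, so that the EEG + HRSD model attains a pooled C index near 0.8 on
  the target item while the HRSD-only model attains about 0.7 — the
  operating point at which the incremental-value analysis is meaningful —
  and then frozen.  An interesting wrinkle found during calibration: with
  only a handful of distinct improvement values, tied-outcome pairs drop
  out of the C index's denominator, so achieved concordances run well above
  what a continuous-normal signal-to-noise calculation predicts; the
  calibration therefore had to be empirical.

What the generator deliberately does **not** emulate: 1/f background
spectra, artifacts (blinks, muscle), eyes-open recordings, volume-conduction
correlations between neighbouring sites, or item-level missingness
patterns.  Passing tests on this generator demonstrate that the pipeline's
statistics behave as specified — they do not certify performance on real
clinical EEG.

## Problem sizes used by the checks

The packaged checks run at desk scale, chosen as the package's own test
conditions: recovery of the planted effect uses 20 independent cohorts of
n = 500 with 10 s recordings (the planted effect acts through the
*standardised* feature, so shortening the recording changes the feature's
noise composition, not the effect's scale); the permutation-null check uses
one cohort of n = 300 with 20 permutations, re-evaluating each selected
configuration on a fresh permutation; the end-to-end determinism check uses
n = 60 with two symptoms, one feature combination and one grid point.
Bootstrap intervals use 1000 replicates where they are the quantity under
test and fewer where they are incidental.

## Known limitations

* The search's reported C index is selection-optimistic (see above); use
  `nested = TRUE` for honest point estimates at extra cost.
* The EDF container is not read; recordings enter via the documented CSV
  matrix dialect or the in-memory `eeg_recording()` constructor.
* Derived band-pair ratio features beyond the beta–alpha ratio (e.g.
  theta–alpha ratios at single sites) are not generated by default; the
  published feature lists include a few such names whose exact definitions
  are not given in any methods text, and the package does not guess them.
* `stratified_folds()` merges sparse outcome classes by value distance;
  with heavily skewed items this can leave one merged class dominating the
  stratification.
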