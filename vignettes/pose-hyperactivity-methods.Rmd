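---
title: "Quantifying preschool hyperactivity from point-of-view pose landmarks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying preschool hyperactivity from point-of-view pose landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

povmotion turns 33-keypoint pose-landmark time series — the per-frame
output of a monocular pose estimator applied to first-person video of a
seated child — into regional movement indices, group statistics, and a
cross-validated hyperactivity-risk classifier. This vignette explains
the model behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic cohort generator does and
does not emulate, and the numerical conventions the implementation
commits to.

## The measurement model

Each session is a `frames x 33` trajectory of (x, y, z) coordinates in
normalized image units plus a per-landmark confidence in [0, 1],
recorded at 30 fps and trimmed to a 180-s window (5,400 frames). The
pipeline is a fixed sequence:

1. **Validity gating.** A (landmark, frame) cell is invalid iff its
   confidence is strictly below 0.50. A session is excluded when the
   fraction of invalid cells over all `33 x frames` cells exceeds 20%.
2. **Gap repair.** Within one landmark's trajectory, maximal invalid
   runs of at most 10 frames (333 ms at 30 fps) are filled by per-axis
   linear interpolation between the nearest valid neighbours. Longer
   interior runs are filled by a constant-velocity Kalman filter run
   over up to 15 valid samples on each side of the gap: a forward pass
   predicts into the gap from the left, a backward pass from the right,
   and the two predictions are cross-faded linearly so the fill stays
   anchored at both ends. Leading and trailing invalid runs hold the
   nearest valid value (no second anchor exists). Valid samples are
   never modified.
3. **One Euro smoothing.** Each axis is passed through a causal One
   Euro filter: an exponential smoother whose cutoff rises with the
   estimated signal speed (`f_c = f_min + beta * |dx_hat|`), so slow
   pose-estimator jitter is suppressed while fast genuine movements pass
   with little lag.
4. **Composites and pelvis root.** Landmarks are aggregated into 17
   region points — head (centroid of the 11 facial landmarks),
   left/right shoulder, elbow, wrist, hand (thumb/index/pinky centroid),
   hip, knee, ankle, foot (heel/foot-index centroid) — and every point
   is expressed relative to the per-frame midpoint of the two hips, so
   indices measure limb and segment motion rather than whole-body
   translation in the image.
5. **Windowed displacement indices.** Frames are partitioned into
   consecutive non-overlapping 5-frame windows (167 ms); each window is
   summarized by its mean position; the regional activity index is the
   sum of Euclidean x–y distances between successive window means over
   the session. Monocular depth is unreliable, so z never enters an
   index. The global activity index is the exact sum of the 17 regional
   indices.

Two exact properties pin the geometry down and are tested as such:
adding any per-frame offset to all landmarks leaves every index
unchanged (pelvis-root invariance), and multiplying all coordinates by
`c > 0` multiplies every index by exactly `c` (the indices are
scale-dependent; no anthropometric normalization is attempted).

## Statistics

Group comparisons use Mann–Whitney U tests with joint midranks. The
reported statistic is `U = min(U1, U2)`; the standardized statistic uses
the tie-corrected normal approximation, the two-sided p comes from the
normal distribution, and the effect size is `r = |Z| / sqrt(N)`. The
Shapiro–Wilk gate (nonparametric iff p < 0.05 in at least one arm) is
applied as a census over the 17 regional indices plus the global index.
Benjamini–Hochberg FDR adjustment runs across the 15 analysis regions
(hips are excluded: under pelvis rooting their indices are
near-degenerate, though they still enter the global sum). A sensitivity
analysis groups outcomes into five a priori anatomical domains — head
(m = 1) and four limb domains (m = 4) — with a per-domain Bonferroni
threshold `0.05/m`, i.e. 0.0125 for each limb domain and no correction
for the head; significance is strict (`p < alpha_adj`, so p = 0.0125
exactly is not significant). Teacher-rating associations use Spearman
correlations with Fisher-z intervals (`SE = 1/sqrt(n-3)`) and
t-approximation p values, deliberately uncorrected for multiplicity
(exploratory). Where only printed summaries are available, the package
recovers the underlying statistics in closed form: a pooled-variance t
from group means/SDs/sizes, a Pearson chi-square for a 2x2 table, and U
from printed group mean ranks (with the rank-sum consistency identity
checked).

## Classification

The feature matrix holds the 15 analysis regions; hips and the global
index are excluded (the global index is a sum of the features and would
leak redundantly). Labels are risk vs control with risk positive. Five
families are evaluated — SVM, random forest, extremely randomized
trees, AdaBoost over depth-1/2 rpart trees (SAMME, implemented
in-package), and a class- and optionally distance-weighted kNN
(implemented in-package) — inside a stratified 5x5 nested
cross-validation: the outer loop estimates generalization, the inner
loop grid-searches hyperparameters on the outer-training portion by
pooled inner out-of-fold ROC-AUC (ties broken by grid order). SVM and
kNN get inverse-frequency class weights normalized so the majority
class has weight 1 — with that normalization, weighting a class is
exactly equivalent to duplicating its rows at an integer ratio — and
train-fold z-standardization; tree ensembles get neither. Default
grids: SVM kernel {rbf, linear}, C {0.1, 1, 10, 100}, gamma {scale
heuristic, 0.01, 0.1, 1}; forests 100/300 trees at depth
unlimited/3/5; AdaBoost 50/200 stumps of depth 1/2 at learning rate
0.1/1.0; kNN k {3, 5, 7, 9} with uniform/distance votes. These grids
are this package's defaults, not a claim about any external analysis.

Reporting follows two conventions worth calling out. First, every
pooled out-of-fold metric (accuracy, precision, sensitivity,
specificity, F1) carries a Wilson 95% interval computed at the metric
value with the **whole-cohort denominator n**, i.e. `k = metric * n`
unrounded. For conditional metrics like specificity this is
statistically unconventional (the natural denominator is the class
size); it is adopted deliberately as the reporting convention this
pipeline reproduces, and the package's `wilson_interval()` is also
available for the conventional choice. Second, AUC is reported both as
the mean ± SD of fold-wise rank AUCs and as the rank AUC of the pooled
out-of-fold scores with a Hanley–McNeil interval
(`Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`); the two differ in general because
AUC is a nonlinear rank statistic. A fold containing a single class has
an undefined AUC and is dropped from the fold mean with a warning.
Permutation feature importance is computed per outer fold on the
held-out data: 20 seeded shuffles per feature, importance = baseline
accuracy minus mean permuted accuracy, averaged over folds. A
demographic-only SVM (age + sex, same nested CV) quantifies how much
of the performance basic demographics could explain.

## The synthetic cohort generator

No recordings ship with the package, so the generator stands in for
them. It is a statistical stand-in for seated-child landmark motion,
not a biomechanical model:

* Each of the 17 regions follows a mean-reverting (AR(1) /
  discretized Ornstein–Uhlenbeck) displacement process around a seated
  base pose, with per-region innovation scale (default around 0.001
  normalized units/frame, larger distally) and mean reversion
  `theta = 0.05`/frame — bounded, fidget-like excursions.
* Kinematic chain coherence: wrists and hands inherit half of the
  elbow displacement, ankles and feet half of the knee displacement.
* The risk arm multiplies region amplitudes: x2.0 at wrists, hands,
  ankles and feet, x1.5 at elbows and knees, x1.1 at shoulders, x1.4
  at the head, x1.0 at hips — the distal-dominant signature the
  analysis is designed to detect.
* Each child carries a lognormal latent activity factor
  (`sdlog = 0.45`) multiplying all amplitudes; the teacher
  hyperactivity score is `round(clip(-14 + 12 * latent + noise,
  0, 30))` with latent = activity factor x arm mean multiplier — the
  simplest model producing a positive rating–movement coupling with
  heavy within-arm overlap, a near-zero control median, and clearly
  elevated risk-arm scores.
* Per-frame Gaussian jitter (`sd = 0.001`) emulates pose-estimator
  noise; confidence dropouts arrive in bursts (Bernoulli starts at
  `rate/(60 fps)` per frame, geometric lengths with mean 5 frames)
  with confidence drawn uniformly from [0, 0.5); z gets its own OU
  process with no group dependence.
* Ages are uniform over 48–60 months; sexes are drawn per arm at 14/20
  (risk) and 15/31 (control) boy proportions.

What it does **not** emulate: camera/teacher head motion, occlusion
structure correlated with movement, left-right dominance, postural
shifts with concurrent pelvis displacement, and — importantly — the
full covariance structure of real child movement. Because one latent
factor drives all regions, synthetic cohorts are more separable
multivariately than real children are: univariate effect sizes land
near 0.5–0.7 under the defaults, but a classifier pooling 15
correlated features denoises the latent factor and approaches perfect
discrimination. Passing tests therefore demonstrate that the pipeline
recovers planted structure correctly, not that any particular
real-data performance level would be attained; published headline
performance numbers are never targets for synthetic runs. For the same
reason, permutation importance on synthetic features is diluted and
reshuffled by collinearity and is checked only for its sign and
ordering properties on constructed problems.

## Numerical choices and degenerate inputs

* "Global missingness" is the fraction of invalid (landmark, frame)
  **cells**, not of frames with any invalid landmark — with 33
  landmarks the per-frame-any reading is pathologically strict. The
  threshold applies strictly (`> 0.20` excludes).
* Confidence exactly 0.50 is valid (the rule is strictly-below).
* Kalman defaults: process noise 1e-4, measurement noise 1e-2 on the
  normalized-units scale; with these, a noise-free constant-velocity
  25-frame gap is recovered to well under 1e-5 (the test asserts 1e-6
  for the blended fill) because both passes converge to the true
  velocity and the cross-fade anchors both endpoints. A forward-only
  variant sits behind `kalman_blend = "forward"`.
* One Euro defaults are the filter's original reference defaults:
  `min_cutoff` 1 Hz, `beta` 0.007, `dcutoff` 1 Hz. The smoother update
  is written in incremental form (`x + a*(new - x)`) so it is exactly
  the identity on constant signals. Gaps are filled before smoothing;
  the reverse order would smooth across invalid samples.
* Window remainder: when the frame count is not a multiple of the
  window, trailing frames are dropped; at exactly 5,400 frames there is
  no remainder.
* The global index includes the hip indices ("sum of all regional
  indices" read literally); both the inclusion and the window/plane
  choices are configurable.
* Grid-search ties resolve to the first grid row; fold assignment
  deals shuffled class members round-robin, keeping per-fold class
  counts within one member. All randomness (folds, forests,
  permutations) derives deterministically from one seed, so a rerun
  reproduces every output bit-for-bit (the pipeline writes an md5
  manifest to make this checkable).
* Degenerate inputs: an all-invalid landmark trajectory is
  unrepairable and forces session exclusion with a logged reason; a
  motionless cohort yields all-zero indices, p = 1 rank tests, empty
  correlation tables (zero variance has no defined correlation), and a
  logged degenerate-features warning rather than an error.

## Problem sizes used by the test suite

The suite regenerates every fixture in code. Calibration uses 500 null
cohorts (identical arms, 20/31, 5-s sessions) to check the 5% size of
the rank test per feature at a 3.5-sigma binomial band, and 100
default-signature cohorts (10-s sessions) to check that ankle/hand
effect sizes exceed shoulder effect sizes and that the movement SVM
beats the demographic baseline; closed-form and oracle checks run on
sessions of 60–5,400 frames. Short sessions are a deliberate choice:
every property being checked (exchangeability, effect ordering,
windowing algebra) is invariant to session length, while full-length
sessions are exercised once in the IO round-trip and in the acceptance
script's full 180-s cohort run.

## Known limitations

Indices are cumulative linear displacements in a pelvis-rooted frame:
scale-dependent (no limb-length normalization), blind to rotation about
the pelvis and to translations the pelvis shares, and summed over time
(no spectral or bout structure). Angular kinematics, velocity spectra
and anthropometric normalization are out of scope. The statistics
reproduce a fixed reporting convention (min-U, normal-approximation p,
whole-cohort Wilson intervals) rather than exact small-sample
inference; permutation-exact p values are not implemented.
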