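---
title: "Methods: from raw IMU streams to behaviour metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw IMU streams to behaviour metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imubehave)
```

## The problem

Sheep spend most of their day in one of three jaw-defined states:
grazing (head down, biting and chewing grass), ruminating (re-chewing a
regurgitated bolus at rest) and non-eating activity (walking, standing or
lying with no jaw movement). Time budgets over these states are sensitive
welfare and health indicators, and a 16 Hz ear- or collar-mounted IMU is
cheap enough, and frugal enough with power, to monitor them continuously.
`imubehave` turns a labelled 16 Hz six-axis stream into a cross-validated
three-class behaviour classifier and the metric tables used to report its
performance.

## Pipeline and assumptions

The pipeline assumes a *uniform 16 Hz* stream (no gap filling or
resampling is attempted), behaviour labels given as intervals on the same
clock, and bouts that are long relative to the 7 s analysis window. Only
the *magnitudes* of the accelerometer and gyroscope are used, never raw
axes, so results do not depend on how the sensor was oriented in its
housing — the property that makes ear and collar mountings comparable at
all.

Four channels are derived: the accelerometer magnitude `A`, the gyroscope
magnitude `G`, and their rates of change `AD`, `GD`. The rate of change
is computed as central differences on interior samples and one-sided
differences at the two stream ends, scaled by the sampling rate. The
scheme was an open choice (a raw first difference would also be
defensible); central differences were picked because they keep all four
channels the same length and index-aligned, which makes windowing
trivial. The alternative differs only by an approximately constant factor
on these signals, which none of the rank-based downstream stages can see.

Windows are `window_s = 7` s long (112 samples) with `overlap = 0.5`
(hop 56). Trailing samples that cannot fill a whole window are dropped:
the windows are defined to be of equal length, so a ragged final window
has no place. A sample at time *t* takes the label of the interval
containing *t* under the half-open `[start, end)` convention, which
prevents double labelling at bout boundaries. A window whose samples all
share one label is *non-mixed*; otherwise it is flagged mixed and gets
its most frequent sample label, with an exact tie broken by the label of
the window's first sample (deterministic and order-stable). Mixed windows
stay in the modelling set under that predominant label by default;
`feature_matrix(..., drop_mixed = TRUE)` excludes them.

## The 44 features

Eleven characteristics per channel, 4 × 11 = 44 named features
(`"A.mean"`, `"GD.spectral_entropy"`, ...). Numerical conventions, all of
which were open choices and are fixed here so results reproduce
bit-for-bit:

* **Kurtosis** is the standardised fourth central moment `m4 / m2²`, with
  population moments, no bias correction and no excess-3 subtraction —
  the simplest variant; any monotone variant yields the same ReliefF
  ordering. A constant window has no defined kurtosis; it is reported as
  0 with a warning.
* **Zero crossings** are strict sign changes of the *mean-centred*
  signal. The magnitude channels are non-negative, so crossings of raw
  zero would be identically zero and the feature degenerate; centring is
  the only reading under which the feature can carry the high rank it is
  known to have. Samples exactly at the mean do not break a sign run.
* **Spectra** are plain (untapered) one-sided periodograms of the
  mean-removed window, bin spacing `fs/N`; the DC bin is excluded from
  every spectral feature. With 112 samples at 16 Hz the bins fall on
  multiples of 1/7 Hz, so a 2 Hz tone sits exactly on bin 14.
* **Dominant frequency** is the frequency of the maximum-power non-DC
  bin, defined as 0 for a degenerate (zero-power) window. **Spectral
  entropy** is the Shannon entropy (natural log) of the normalised non-DC
  power, 0 for a tone on an exact bin and `log(56)` for a flat spectrum.
  **Spectral area** is the non-DC amplitude-spectrum sum times the bin
  width, linear in the signal.

Two published enumerations of the eleven characteristics exist and differ
in one member: one lists an *absolute signal area*, the other a *spectral
area* and no absolute area. Both cannot simultaneously be the extracted
set, and which produced the published rankings is not decidable from the
text; both are implemented (`characteristic_set("table3")` /
`"section25"`) with `table3` — the spectral-area variant — as the
default, because the feature-ranking analysis is stated in those names.

## ReliefF

`relieff_weights()` implements multiclass ReliefF. For each pivot
instance R of class c and each feature f, the weight is decreased by the
mean range-normalised difference to R's k nearest *hits* (same class) and
increased by the prior-weighted mean difference to its k nearest *misses*
in each other class C, weight `P(C)/(1 − P(c))`, all divided by the
number of pivots; weights therefore lie in [−1, 1]. Choices the algorithm
statement leaves open, fixed as follows:

* **Distance** between instances is Manhattan on the range-normalised
  features — the standard choice for Relief-family algorithms.
* **Neighbour ties** are broken by instance index, making the exhaustive
  variant fully deterministic and invariant to row order.
* **`k = 100`** by default. The published parameter "n = 100" is read as
  the neighbour count, because its definition calls it the number of
  neighbours to consider; the alternative reading (number of sampled
  pivots) is exposed as `n_sampled`. Exhaustive pivoting (every instance)
  is the default; `k` is clipped per class, with a warning, when a class
  is smaller than k + 1.
* **Zero-range features** cannot be normalised; they get difference 0,
  hence weight 0, with a warning.
* **Ranking ties** are broken lexicographically by feature name.

The test suite holds the implementation to 1e-9 agreement with a
brute-force scalar-loop oracle on toy problems (≤ 60 instances, 3
classes, k ≤ 3).

## Cross-validation and learners

`stratified_folds()` deals each class's shuffled indices round-robin into
the folds (per-class counts differ by at most one), `run_cv()` trains on
nine folds and tests on the tenth so that every instance is predicted
exactly once, and the pooled confusion matrix accumulates all
predictions. The headline accuracy is the mean of per-fold accuracies;
the pooled-matrix accuracy equals their instance-weighted mean exactly.

The learners are deliberately conventional baselines — the contribution
is the pipeline, not the classifiers — and their defaults are surfaced in
`hyper`: random forest with 500 trees; RBF-SVM with C = 1, standardised
on the training folds only; distance-weighted kNN with k = 5 (weight
1/d); AdaBoost as SAMME over 100 depth-1 `rpart` stumps. Random forest
and AdaBoost are seeded per fold, so identical inputs give identical
results for all four learners.

The feature ranking is computed **once on the full data set** and reused
across folds. This mirrors the sequential procedure the pipeline
reproduces (selection stage, then evaluation stage) and is the
conventional presentation in this literature; it does leak ranking
information into the folds. Since the ranking is the quantity under
study here — the learners never see labels from their test folds — the
package keeps this as the default, and the statistically cleaner
alternative (re-ranking inside each training fold) is a one-line
composition of `relieff_weights()` on the training subset.
`sweep_feature_counts()` evaluates each learner at each feature count
1..44 and reports the maximum with the *smallest* feature count on ties,
favouring parsimonious few-feature operation.

## Confusion-matrix metrics

All metrics are ratios of TP, FN, FP, TN read off the matrix (rows =
observed, columns = predicted), so matrices supplied in percent — the
form in which published tables print — behave identically to counts; the
percent input is treated as exact, with no attempt to recover integer
counts. A class with an empty row or column has its affected metrics
*undefined*, reported as `NA` rather than 0, because silent zeros corrupt
macro averages; macro averages are taken over the unrounded per-class
values. Display rounding is round-half-up to integer percent (matching
the convention of the published tables), with full precision retained in
the report object.

## The synthetic generator

`generate_trial()` emulates only what the analysis actually relies on:

* a bout schedule tiling the trial (uniform lengths in `bout_length_s`,
  default 30–90 s, no behaviour immediately repeated), bouts long
  relative to the 7 s window;
* per axis, acceleration = bout-constant orientation offset + sinusoid at
  the regime's oscillation frequency + white noise; gyroscope axes carry
  the rhythm scaled by `gyro_scale`, without the gravity offset;
* regime defaults chosen once as field-plausible: ruminating
  (magnitude offset 0.95, 1.0 Hz chew rhythm, low noise) < grazing
  (1.30, 1.5 Hz bite rhythm) < non-eating (1.80, faster and much noisier,
  i.e. broadband) on mean accelerometer magnitude — the qualitative
  ordering reported for the real signals, which is the only quantitative
  constraint the source material offers; the distinct frequencies make
  the spectral features behaviourally informative. Ear placement scales
  the gyroscope channels up by 1.5 and changes nothing else.

What it does **not** model: biomechanical realism, individual-animal
variation, sensor drift or bias, gravity direction changes within a bout,
label noise from manual annotation. Consequently a high synthetic
cross-validation accuracy demonstrates that the pipeline's stages are
correct and well-wired — features separate what the generator makes
separable — and says nothing about accuracy on field recordings, which is
why the published collar confusion matrix, not the synthetic experiment,
is the package's exact verification surface for the metric stage.

## Problem sizes and determinism

The shipped tests exercise windows of 112 samples, toy ReliefF problems
of ≤ 60 instances, and an end-to-end synthetic experiment of a 2 h trial
(~2050 windows, about a tenth of the published real experiment), chosen
so the full suite runs in well under a minute on a laptop core while
still crossing the 2000-window scale at which fold stratification and
exhaustive ReliefF are meaningfully exercised. Every stochastic stage
(trial generation, pivot subsampling, fold assignment, seeded learners)
runs under an explicit seed through a private RNG stream that leaves the
caller's `.Random.seed` untouched.

## Known limitations

* Single fixed sampling rate per stream; no multi-rate or gap handling.
* No per-axis features, wavelet features or orientation (quaternion)
  features.
* No hyperparameter search; the learner defaults are baselines.
* ReliefF has no missing-value handling (complete matrices only).
* The synthetic generator's regimes are package choices, not measured
  animal parameters; published real-data rankings and accuracies cannot
  be reproduced from it, only the structural properties (feature counts,
  metric algebra, ranking behaviour, CV mechanics) are verifiable.
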