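# imubehave

Classification of sheep eating behaviour — **grazing**, **ruminating** and
**non-eating** — from ear- or collar-mounted inertial measurement units
(tri-axial accelerometer + tri-axial gyroscope, 16 Hz). Automatic
recognition of these behaviours from wearable sensors is a core tool of
precision livestock monitoring: rumination and grazing time are sensitive
early indicators of health and welfare problems in ruminants, and
low-sampling-rate IMUs make continuous monitoring energy-feasible.

The package implements the full analysis pipeline and is aimed at
researchers in biologging / animal behaviour who want a tested, seeded,
end-to-end reference implementation they can point at their own sensor
CSVs.

## The method

1. **Derived channels.** From the six axes, the orientation-invariant
   magnitudes

   A = √(Ax² + Ay² + Az²)  and  G = √(Gx² + Gy² + Gz²)

   plus their time derivatives *AD*, *GD* (central differences, scaled by
   the sampling rate).
2. **Windowing.** Each channel is discretised into 7 s windows with 50 %
   overlap (112 samples, hop 56 at 16 Hz). A window spanning a behaviour
   transition is flagged *mixed* and assigned its predominant sample
   label.
3. **Features.** 11 characteristics per channel — mean, standard
   deviation, kurtosis, min, max, interquartile range, signal area, zero
   crossings (of the mean-centred signal), dominant frequency, spectral
   entropy and spectral area — giving **44 named features per window**.
4. **Feature selection.** Multiclass **ReliefF**: each feature is scored
   by contrasting every instance's k nearest same-class neighbours
   (*hits*) against its k nearest neighbours in each other class
   (*misses*), miss contributions weighted by class priors
   P(C)/(1 − P(class)); differences are range-normalised so weights lie
   in [−1, 1]. Default k = 100, exhaustive pivots, Manhattan distance.
5. **Evaluation.** Stratified 10-fold cross-validation of four learner
   types (random forest, RBF-SVM, distance-weighted kNN, AdaBoost/SAMME
   stumps) across feature counts 1..44.
6. **Metrics.** From the pooled 3×3 confusion matrix (rows = observed,
   columns = predicted): per class, precision = TP/(TP+FP),
   recall = TP/(TP+FN), F-score = harmonic mean, specificity =
   TN/(TN+FP); overall accuracy = trace/total. All are ratios, so
   matrices given in percent work identically to counts.

A seeded synthetic-trial generator (`generate_trial()`) emulates the
qualitative structure of the real signals — ruminating has the lowest
accelerometer magnitude, non-eating the highest, and each behaviour has
its own oscillation rhythm — so every stage is testable without animal
data.

## Worked example

```r
library(imubehave)

trial <- generate_trial(trial_config(duration_s = 900, seed = 7))
ws <- discretise(build_channels(trial$stream), trial$track)
print(ws)
#> Window set: 256 windows of 112 samples (hop 56 samples, 50.0% overlap)
#> Labels: grazing=71, non_eating=100, ruminating=85
#> Mixed windows: 12.89%

fit <- imubehave(feature_matrix(ws), n_features = 10, relieff_k = 50, seed = 7)
print(fit)
#> Eating-behaviour classifier (random_forest, 10 ReliefF-selected features)
#> Classes: grazing, non_eating, ruminating
#> 10-fold CV mean accuracy: 0.9843
#> Top features: A.mean, A.signal_area, G.mean, G.signal_area, AD.spectral_area ...

summary(fit)
#>            Precision Recall F-score Specificity
#> grazing    100%      97%    99%     100%
#> non_eating 98%       99%    99%     99%
#> ruminating 98%       99%    98%     99%
#> Overall    98%
```

Reading the output: 900 s of synthetic trial yield 256 overlapping 7 s
windows, of which 12.9 % straddle a behaviour change. `imubehave()` ranks
the 44 features by ReliefF, keeps the top 10, and the 10-fold
cross-validated random forest recovers the three behaviours almost
perfectly — the synthetic regimes are deliberately well separated, so
this is a pipeline check, not a claim about field data. `summary()`
derives the per-class metric table from the pooled cross-validation
confusion matrix, rendered as round-half-up integer percentages.

Applying the pipeline to real recordings is the same composition starting
from `read_sensor_stream()` / `read_label_track()`; a published collar
confusion matrix is bundled for metric verification:

```r
cm <- read_confusion_csv(system.file("extdata",
        "collar_confusion_percent.csv", package = "imubehave"),
        unit = "percent")
print(confusion_to_metrics(cm))
#>            Precision Recall F-score Specificity
#> grazing    96%       93%    95%     98%
#> non_eating 89%       95%    92%     92%
#> ruminating 92%       87%    89%     97%
#> Overall    92%
```

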