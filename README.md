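# graspid — subject-specific grasping pattern analysis

When different people grasp the same object, are the resulting movement and
force patterns individual enough to tell the people apart? `graspid` is an R
package for answering that question from synchronized optical motion-capture
and fingertip force recordings. It implements the complete chain used in
grasp-biometrics studies — and, because such datasets are rarely public, a
synthetic multi-subject grasp-trial generator so every stage is testable
end to end.

## The analysis in brief

A trial is one prehension movement: **reach** (movement onset to object
contact), **grasp** (contact to release), **release** (release to rest).
From 20 hand markers (120 Hz) and 5 fingertip force channels (960 Hz) the
package extracts 15 feature series per trial:

- **θ₁** per digit — the angle between the palm-plane normal **N** (from the
  three palm markers) and the line from the palm-marker centroid to the
  digit's proximal marker (thumb: metacarpal marker);
- **θ₂** per digit — the flexion angle between successive phalange segment
  directions (0° = straight finger);
- **F** per digit — the fingertip normal force, converted from sensor
  voltage through a per-subject spring-platform calibration
  (*F = k Δx*, spring constant *k* = 0.45 N/mm, isotonic fit).

Trajectories are low-pass filtered at 15 Hz (zero-phase Butterworth); force
channels are notch-filtered at 50 Hz (mains), decimated 960 → 120 Hz and
converted to newtons. Each series is resampled to 500 samples, giving a
15 × 500 matrix per trial, flattened to a 7500-vector (5000 angles-only)
and z-normalized with pooled statistics (angles and forces separately).

Classification: exact t-SNE embedding to 2–3 dimensions (perplexity 10–15
for per-object subject clustering, 50 for object-level grip types), then
weighted k-nearest neighbours with weights *wᵢ = dᵢ⁻²*, *k* = 10, scored by
seeded stratified 5-fold cross-validation; the mean fold accuracy is the
quality of clustering. The sensitivity analysis re-scores the pipeline for
**every feature subset of sizes 2–14** (32,751 subsets), replacing excluded
features by N(0, 1) noise, averaging 3 repeats, and averaging per-object
quality vectors — yielding per-size max/mean/min profiles, best-*k*
subsets, and a time-window variant.

## Worked example

Simulate a small study (8 subjects × 2 objects × 5 trials), extract
features, and classify subjects for one object:

```r
library(graspid)

cfg <- grasp_config(n_subjects = 8, n_objects = 2, n_trials_per_object = 5,
                    subject_effect_scale = 8, trial_noise_scale = 1.5, seed = 42)
rec      <- generate_dataset(cfg)
ext      <- extract_features(rec)              # filter, segment, assemble
datasets <- build_object_datasets(ext$matrices, hand_sizes = hand_sizes(rec))

cv <- cross_validate(datasets$O1, perplexity = 12, seed = 1)
cv
#> Cross-validated weighted kNN (k = 10, 5 folds, split after_embedding)
#>   mean accuracy: 100.00%
#>   per-fold: 100.0%, 100.0%, 100.0%, 100.0%, 100.0%

confusion_by_hand_size(cv)$subject_order     # confusion matrix, smallest hand first
#> [1] "S01" "S02" "S07" "S03" "S06" "S05" "S04" "S08"
```

With a subject effect of 8° against 1.5° of trial noise, the 40 trials of
object `O1` separate into 8 clean per-subject clusters, so every
cross-validation fold classifies perfectly — the strong-signal regime. The
hand-size ordering is the diagnostic view: misclassifications (here none)
concentrating near the diagonal would indicate confusion between similarly
sized hands.

A reduced sensitivity scan on feature-level data with 4 planted informative
features (1, 2, 3, 7 of 8) finds them:

```r
d  <- simulate_feature_dataset(n_subjects = 6, n_trials = 5, n_features = 8,
                               n_samples = 40, informative = c(1, 2, 3, 7), seed = 9)
sc <- sensitivity_scan(d, enumerate_subsets(8, 2, 7), n_repeats = 3,
                       seed = 9, perplexity = 8, n_iter = 300)
size_profile(sc)
#>   size   min  mean   max
#>      2 0.133 0.335 0.578
#>      3 0.089 0.421 0.800
#>      4 0.133 0.524 0.867
#>      5 0.200 0.644 0.933
#>      6 0.400 0.773 0.989
#>      7 0.767 0.890 0.989
best_subset(sc, 4)$subset
#> [1] 1 2 3 7
```

The max-quality curve plateaus once all informative features fit in the
subset and declines steeply below that size — the signature shape of the
feature-importance analysis.

See `vignettes/grasp-pattern-analysis.Rmd` for the full account of the
models, conventions and design choices, and `inst/cli/graspid.R` for a thin
command-line wrapper (`simulate`, `pipeline` subcommands).

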