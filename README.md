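# motionprint

Per-user motion-sensor biometrics for shared-tablet use measurement.

## The problem

Passive-sensing apps can log *that* a family tablet is in use, but not
*which child* is using it — a real obstacle for research on children's
device use, where siblings and parents share devices. Behavioral
biometrics offers a fix: a child's micro-movements while holding a tablet
(captured by the built-in 100 Hz accelerometer and gyroscope) are
distinctive enough to train a per-child authentication model.

`motionprint` implements that pipeline end to end and, crucially, the
experiments that ask **what kind of training data such a model needs**:

* **Unseen negatives ("decoys")** — children present in the test data but
  deliberately excluded from all training, simulating unknown household
  members.
* **Training length** — 1 through 12 minutes.
* **Time proximity** — how far the training window sits from the test
  window within a session.
* **User position** — training/testing while laying vs sitting.

Since no public child cohort of this kind exists, the package ships a
seeded synthetic generator as a first-class module: 36 simulated children
follow a sedentary protocol (10 min laying, then 5 min sitting, 100 Hz),
each with a stable movement signature (position-dependent device
orientation, per-axis tremor sinusoids, sensor noise) and slow bounded
attitude drift. The generator defines the study conditions; results are
qualitative reproductions of field findings, not re-estimates of any real
cohort's numbers.

## The method in brief

Streams are cut into non-overlapping 1-second windows. Each window yields
a 56-feature vector — {mean, max, min, RMS, variance, SD, skewness, excess
kurtosis} × {yaw, pitch, roll, accelX, accelY, accelZ, vector magnitude} —
with pitch/roll from accelerometer tilt, yaw from per-window gyroscope
integration, and min–max normalization fit on training windows only.
One-vs-rest models per target child:

* k-nearest neighbours (k ∈ {5, 10, 100, 200}),
* random forest (max depth ∈ {10, 50, 100}, via `ranger`),
* a feed-forward neural network (100 rectified hidden units, Adam, L2
  strength ∈ {10⁻¹ … 10⁻⁵}),

each tuned by exhaustive grid search with stratified threefold
cross-validation selecting on positive-class F1 — plus a compact
dual-stream transformer over raw 100 × 6 window sequences (a temporal
stream and an FFT-magnitude frequency stream, each a strided convolution +
self-attention encoder, mean-pooled, concatenated into an MLP head; all
gradients hand-derived and finite-difference-verified). Per-target
precision/recall/F1/accuracy are aggregated across the 32 targets as
median and interquartile range.

## Worked example

Identify child `user01` from one minute of training data recorded
immediately before the test block (the most favourable proximity):

```r
library(motionprint)

cohort <- build_cohort(n_users = 36, seed = 1, separation = 1)
#> <cohort_data> 36 users, 32400 windows, separation 1.00, seed 1

targets <- cohort_targets(cohort$users, seed = 1)
spec <- build_length_sweep(cohort$users, targets[1], "backward_trim",
                           minutes = 1, seed = 1)
#> <experiment_spec> rq3_backward target=user01 decoys={user06,user09,user17,user33}
#>                   train=32 test=10 gap=0

res <- run_experiment(spec, "knn", cohort)
res$metrics
#> <metrics_set> TP=98 FP=0 TN=480 FN=22 | P=1.000 R=0.817 F1=0.899 acc=0.963
```

The model saw 1,920 training windows (1 minute × 32 enrolled children)
and was tested on 600 windows: the target's last two sitting minutes plus
the same minutes from four decoy children it never trained on. Precision
1.0 means no decoy or other-child window was mistaken for the target;
recall 0.817 means ~82% of the target's windows were recognized. Across
all 32 targets of this cohort:

```r
specs <- lapply(targets, function(tg)
  build_length_sweep(cohort$users, tg, "backward_trim", minutes = 1, seed = 1))
summarize_metrics(run_knn_cell(specs, cohort, k = 5))
#>      metric median       q25 q75 n_targets
#> 1 precision      1 0.9663537   1        32
#> 2    recall      1 0.9812500   1        32
#> 3        f1      1 0.9084942   1        32
#> 4  accuracy      1 0.9608333   1        32
```

Median F1 of 1.0 with one adjacent minute of training — while the same
pipeline trained on far-away, different-position minutes scores near 0 —
is the package's core finding on its synthetic cohort: *proximity and
position of the training data matter far more than its length*.

The full pipeline is also scriptable: `run_config()` +
`cmd_simulate()` / `cmd_run()` / `cmd_report()` write a cohort of
SensorLog-style CSVs, execute the configured experiment families
resumably, and render per-family CSV tables, figures and a provenance
manifest (see `inst/scripts/motionprint.R` for the command-line wrapper,
and the methods vignette in `vignettes/` for all modeling conventions).

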