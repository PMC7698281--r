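# breathdetect

Detection and classification of breathing patterns — normal breathing,
central sleep apnea (CSA), obstructive sleep apnea (OSA), cough, sigh, yawn —
from 12-channel wearable inertial sensor signals (chest + abdomen, tri-axial
accelerometer + gyroscope, 125 Hz).

The package is aimed at researchers in digital respiratory monitoring who
want a fully reproducible, CPU-sized version of the synthetic-injection
training pipeline used for wearable apnea detection:

1. **Simulate** annotated acquisition sessions (`simulate_subject_session()`):
   300 s of normal breathing, one 30-s breath hold (CSA), five repetitions
   each of yawn, cough, sigh and Mueller-maneuver OSA, in seeded-random
   order. OSA clips carry the clinical hallmark of paradoxical breathing:
   chest and abdomen respiratory components in anti-phase.
2. **Build datasets** (`extract_event_pool()`, `build_detection_dataset()`):
   30-s segments (3750 samples) of normal breathing with 0, 1 or 2 event
   clips spliced in. A lone CSA event lasts 10, 20 or 23 s; in two-event
   segments a CSA lasts 10, 11 or 13 s, the first event sits in the first
   15 s and the second in the last 15 s. Splice boundaries are smoothed by
   averaging the edge samples with their normal-breathing neighbors, each
   segment carries one label per second, and segments are split 60/20/20.
3. **Train 1D CNNs** (`build_classifier()`, `build_detector()`,
   `train_model()`): an AlexNet-style window classifier (6 conv + 4 dense
   layers, 7-s windows = 875 steps × 12 channels = 10,500 inputs) and a
   residual per-second detector (stem conv + 4 residual blocks with widths
   doubling 64→512, time-distributed softmax head emitting a 6-class
   probability row per second). The conv/batch-norm engine, backprop,
   RMSprop/Adam and the reduce-on-plateau schedule are implemented in the
   package; training is deterministic under a seed. A `desk` preset trains
   in minutes on one CPU; the `full` preset mirrors the full-scale
   architecture (~2×10⁸ parameters).
4. **Evaluate** (`classification_report()`, `roc_curve_auc()`,
   `detection_lag()`): per-class precision/recall/F1 with support
   (F1 = 2PR/(P+R)), confusion matrices in counts and row percentages,
   ROC/AUC, and signed onset-lag statistics for matched event spans.

## Worked example

```r
library(breathdetect)

sessions <- lapply(1:4, function(i)
  simulate_subject_session(seed = 100 + i, subject_id = sprintf("S%03d", i)))
pool <- extract_event_pool(sessions)
pool
#> <event_pool> csa=4 cough=20 osa=20 sigh=20 yawn=20 | 88 normal reservoir spans

ds <- build_detection_dataset(pool, n_segments = 120, seed = 7)
model <- build_detector(detector_config("desk"))
fit <- train_model(model,
                   train = ds$segments[ds$split$train],
                   val   = ds$segments[ds$split$validation],
                   hyper = list(epochs = 10, batch_size = 16), seed = 7)
ev <- evaluate_detector(fit, ds$segments[ds$split$test])
ev$report
#> <eval_report> 720 instances
#>   class precision recall   f1 support
#>  normal      0.96   0.99 0.97     430
#>     csa      0.97   0.99 0.98     182
#>   cough      1.00   0.14 0.25       7
#>     osa      0.95   0.93 0.94      60
#>    sigh      0.00   0.00 0.00       3
#>    yawn      1.00   0.84 0.91      38
#> macro F1 0.676 | weighted F1 0.958

detection_lag(labels_to_spans(ev$truth), labels_to_spans(ev$predicted))
#> <lag_report> 25 matched events (mean lag +0.40 s), 3 unmatched
```

The report reads like any per-class detection table: each of the 720
held-out seconds (24 test segments × 30 s) gets one predicted label;
`support` counts the true seconds per class. In this four-minute demo the
frequent classes are already solved while the rare short events (7 cough
seconds, 3 sigh seconds in the test split) are not — at the package's
reference size (10 subjects, 500 segments, 18 epochs; see the acceptance
script) the same detector reaches per-second macro F1 ≈ 0.97 with all six
classes above 0.85. The lag report matches each true event span to the
same-class predicted run with the largest overlap; a mean lag of +0.40 s
means onsets are predicted slightly late on average.

A command-line front end over the same functions lives in
`inst/cli/breathdetect-cli.R` (`simulate`, `build-dataset`, `run-all`).

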