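# eegdep

Frontal six-channel EEG classification of depressive disorder (DD) versus
healthy controls (HC), for researchers building or evaluating
EEG-based screening pipelines.

Resting-state EEG carries band-specific group differences between DD
patients and controls — most prominently elevated beta-rhythm
(13–30 Hz) power over the frontal cortex. This package implements the full
analysis chain for the practical low-density setting of six frontal
electrodes (Fp1, Fp2, F3, F4, F7, F8):

* **Synthetic cohorts** — a generator producing two-group EEG with
  1/f^α background, band-limited oscillations with controllable DD/HC
  band-power ratios, per-subject amplitude variability, and
  spatially-stereotyped ocular artifacts; since clinical cohorts of this
  kind are not publicly deposited, this is the ground-truth test bed for
  every downstream stage.
* **Preprocessing** — downsampling 250 → 125 Hz, baseline (DC) correction,
  FastICA ocular-artifact removal, non-overlapping 4-s epoching, and
  4th-order Butterworth band filtering into the canonical rhythms
  (theta 4–8, alpha1 8–10, alpha2 10–13, beta 13–30 Hz) or wide bands
  (4–30, 8–30, 10–30 Hz).
* **Models** — two multi-resolution 1-D CNN classifiers, implemented
  natively with analytic gradients (C++ kernels for the hot loops):
  - **MRCNN-RSE**: parallel conv branches (kernels 4-3-3 / 10-3-3,
    batch-norm + GELU), residual squeeze-and-excitation channel
    recalibration, temporal self-attention with two add-and-normalize
    stages, softmax head;
  - **MRCNN-LSTM**: three parallel conv branches (ReLU) feeding an LSTM,
    a fully connected layer with dropout, softmax head.
* **Training / evaluation** — AdamW with the warmup schedule
  5e-5 → 1e-3 (20 epochs) → cosine decay → 5e-4, batch 32, weight decay
  1e-3; stratified epoch-level or leakage-free subject-level k-fold
  cross-validation; confusion-matrix metrics
  (accuracy = (TP+TN)/N, precision = TP/(TP+FP), recall = TP/(TP+FN),
  F1 = 2TP/(2TP+FP+FN)) reported as mean ± SD across folds.
* **I/O** — EDF read/write, an exact float64 array-on-disk format with
  JSON sidecars, YAML run configs, JSON manifests/reports, and a CLI
  (`inst/cli/eegdep`) with `simulate | preprocess | train | evaluate | run`
  subcommands.

## Worked example

Generate a cohort with a planted beta-band effect, verify the plant with
the periodogram oracle, preprocess into beta-band epochs, and
cross-validate the MRCNN-RSE classifier (scaled-down filters for a quick
CPU run):

```r
library(eegdep)

spec <- cohort_spec(n_group_a = 8, n_group_b = 8, duration_s = 60,
                    artifact_rate = 0, seed = 42)
cohort <- generate_cohort(spec)
planted_effect_summary(cohort, "beta")
#> <band_effect_summary> 13-30 Hz: HC 15.6 uV^2, DD 30.7 uV^2, ratio DD/HC = 1.971

epochs <- preprocess_cohort(cohort, pipeline_config(band = "beta", ica = FALSE))
epochs
#> <eeg_epochs> 240 epochs x 6 ch x 500 samples @ 125 Hz, band 13-30 Hz (zero-phase)
#>   labels: DD=120, HC=120 | 16 subjects

cfg <- train_config(max_epochs = 15, warmup_epochs = 5, n_folds = 3, seed = 1)
rep <- cross_validate(epochs,
  model_spec("mrcnn_rse", conv_filters = c(4, 4, 4), se_reduction = 4), cfg)
rep
#> <cv_report> 240 epochs, band 13-30 Hz, 3 folds (epoch_level), positive = DD
#>   Accuracy 95.42 +/- 0.59% | F1 95.54 +/- 0.60% | Precision 92.91 +/- 0.08% | Recall 98.33 +/- 1.18%
```

The default cohort plants a 1.8× DD/HC beta-power ratio; the measured
ratio (1.97 here) sits within sampling error of the plant for this cohort
size. The classifier separates the groups at 95% held-out accuracy on the
beta band, while the same pipeline on a band with no planted effect stays
near chance — the band-resolved ordering the method is designed to expose.
`fold_unit = "subject_level"` switches to leakage-free whole-subject folds.

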