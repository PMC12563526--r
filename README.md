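# fmdetect

Lightweight fetal-movement detection from wearable IMU signals, as a
complete, tested R pipeline.

## The problem

Fetal movement monitoring traditionally relies on maternal perception or
clinical ultrasound, both with obvious limitations for continuous home
use. A wearable abdominal patch with a six-axis inertial measurement
unit (3-axis accelerometer in g, 3-axis gyroscope in deg/s, 190 Hz) can
record movement around the clock — but the classifier must run on a
microcontroller, and fetal-movement (FM) windows are rare: roughly 1073
FM against 32,770 non-FM (N-FM) 5 s windows in a 120-subject cohort.

`fmdetect` implements the full detection pipeline for this setting:

1. **Synthetic cohort generation** with dual-confirmation labels
   (maternal button presses validated by ultrasound intervals),
   including a registered *study-scale fixture* whose per-subject window
   and event counts are a fixed table, reproducing the cohort above
   exactly for any seed.
2. **Segmentation and leakage-free splitting** — non-overlapping 5 s
   windows, labeled FM only under dual confirmation; subjects (never
   segments) are assigned 80/20 to train/test and the training side
   80/20 again to train/validation.
3. **Virtual-rotation augmentation** of the FM minority: each copy
   rotates both sensor triples with a fresh unit quaternion
   (per-axis angles uniform in ±15°), `v' = q⁻¹ (0, v) q`, emulating a
   different sensor mounting; ×10 expansion takes 686 FM training
   segments to 6860.
4. **Adaptive k-means undersampling** of the N-FM majority (k = 12,
   ≤300 iterations, tolerance 1e-4) with a composite distance
   `0.7·L1/d + 0.3·(1 − cos)` and stratified dual-criterion selection
   (Manhattan centrality alternating with cosine diversity) down to the
   balanced count.
5. **STFT spectrograms** — six channels merged to three per-axis
   channels (`zscore(accel) + zscore(gyro)`), Hamming window of 256
   samples with 50% overlap, dB magnitudes, global train-split
   standardization: a 3 × 129 × 6 image per segment.
6. **Knowledge distillation** — compact students (inverted-residual
   0.32 M, channel-shuffle 0.31 M, fire-module 0.27 M parameters)
   trained from a larger residual teacher with the loss
   `(1−α)·H(y, s(z_s)) + α·T²·KL(s(z_t,T) ‖ s(z_s,T))`,
   Adam, early stopping on validation loss, exhaustive grid search over
   T ∈ {1,3,5,7,9}, α ∈ {0.3,0.5,0.7}, learning rate, batch size and
   dropout.
7. **INT8 post-training quantization** (per-channel symmetric weights,
   per-tensor asymmetric activations, fake-quant emulation), payload
   accounting, sensitivity/precision/F1 reporting, Pareto trade-off
   tables, and a duty-cycle battery-life estimator.

The convolutional engine is implemented in the package itself (NHWC
layers with compiled im2col/depthwise kernels) — no external deep
learning runtime is required.

## Worked example

A desk-scale run of the whole pipeline (a few minutes on one CPU):

```r
library(fmdetect)

## a small cohort: 8 subjects, ~11 min sessions, clearly perceptible bursts
cfg <- fm_cohort_config(n_subjects = 8, session_duration_s = 652.5,
                        fm_prevalence = 0.10)
cohort <- generate_cohort(cfg, seed = 42)
segs <- do.call(bind_segments, lapply(cohort, segment_and_label))
print(segs)
#> <fm_segments> 1040 segments (108 FM / 932 N-FM), window 950 samples, 8 subjects

folds <- split_subject_independent(segs, split_spec(seed = 42))
fm  <- folds$train[folds$train$label == "FM"]
nfm <- folds$train[folds$train$label == "N-FM"]

## balance the training split: x4 rotation augmentation, then cluster-based
## undersampling of the majority down to the same count
fm_aug  <- augment_minority(fm, 4, seed = 1)
nfm_sel <- undersample_majority(nfm, length(fm_aug), k = 6, seed = 1)
train <- bind_segments(fm_aug, nfm_sel)
print(train)
#> <fm_segments> 528 segments (264 FM / 264 N-FM), window 950 samples, 5 subjects

## spectrograms, normalized with training-split statistics only
x_train <- spectrogram_batch(train)
stats <- fit_global_stats(x_train)
x_train <- (x_train - stats$global_mean) / stats$global_sd
attr(x_train, "labels") <- train$label
x_val <- spectrogram_batch(folds$validation, stats)

## distill a 0.32 M-parameter student from a residual teacher
teacher <- fm_train("teacher_large", x_train, x_val = x_val,
                    batch_size = 64, max_epochs = 12, patience = 3, seed = 7)
student <- fm_train("student_inverted_residual", x_train, x_val = x_val,
                    teacher = teacher, temperature = 3, alpha = 0.5,
                    batch_size = 64, max_epochs = 12, patience = 3, seed = 7)
summary(student)
#> Family        : student_inverted_residual
#> Parameters    : 0.32 M
#> Distilled     : yes (T=3, alpha=0.5)
#> Epochs run    : 12 (best 10, patience 3)
#> Validation    : SEN 100.00%  PRE 60.87%  F1 75.68%

## INT8 post-training quantization with a paired report on the test split
qm <- calibrate_and_quantize(student, x_train)
x_test <- spectrogram_batch(folds$test, stats)
quantized_performance_report(student, qm, x_test)
#>   metric    float quantized delta_pp
#> 1    SEN 89.28571  89.28571        0
#> 2    PRE 65.78947  65.78947        0
#> 3     F1 75.75758  75.75758        0

model_size_bytes(student$model, "float32")
#> [1] 1272200   (1.21 MB)
model_size_bytes(qm, "int8")
#> [1] 334998    (0.32 MB)

## how long would a 1000 mAh battery last at 135 mW idle / 179.8 mW peak?
estimate_battery_life(1000, fm_power_profile())
#> [1] 26.42609
```

Interpretation: on held-out subjects the distilled student finds nearly
every FM window (high sensitivity) but, with only ~260 genuine training
windows behind it, still over-calls movement on background windows
(moderate precision) — typical for a cohort this small. Quantization to
INT8 leaves the decisions on this test split unchanged while shrinking
the parameter payload 3.8-fold (1.21 MB to 0.32 MB), and the duty-cycle
power model puts continuous operation at roughly a day per 1000 mAh.
At the study's full scale (120 subjects, x10 augmentation, undersampling
to 6860 + 6860) the same functions run unchanged; see below.

A command-line driver covering the same steps
(`synth`, `segment`, `augment`, `undersample`, `spectrogram`, `train`,
`distill`, `quantize`, `sweep`, `report`) is installed at
`system.file("cli", "fmpipe.R", package = "fmdetect")`.

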