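---
title: "Detecting fetal movement from wearable IMU signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fetal movement from wearable IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A pregnant wearer carries an abdominal patch with a six-axis inertial
measurement unit (IMU): a 3-axis accelerometer (g) and a 3-axis gyroscope
(deg/s), both sampled at 190 Hz. The task is to decide, for every
non-overlapping 5 s window, whether it contains a fetal movement (FM) or
not (N-FM). Ground truth comes from a dual-confirmation protocol: the
mother presses a marker button when she perceives movement, and a
clinician confirms movement intervals by real-time ultrasound. A window
is FM only when a confirmed interval overlaps it *and* a press falls
within a coincidence tolerance of that interval; perception without
confirmation, or confirmation without perception, stays N-FM.

Real cohorts of this kind are private, so `fmdetect` ships a synthetic
cohort generator that reproduces the statistical structure the pipeline
depends on, together with a registered *study-scale fixture*: a
120-subject cohort whose segmentation yields exactly 1073 FM and 32,770
N-FM windows, split subject-independently into 686/20,973 (train),
172/5,243 (validation) and 215/6,554 (test) FM/N-FM segments. The
per-subject window and event counts are a fixed table
(`fixture_manifest()`), not random draws, so these counts hold for any
seed while the waveforms themselves vary.

## The synthetic signal model

Each recording is background plus sparse FM bursts:

* **Background** — white sensor noise (`noise_sd`, default 0.02 g; the
  gyroscope scales it by `gyro_unit_scale` = 50 deg/s per g), slow
  sinusoidal baseline drift (`drift_sd`, default 0.01 g, 0.005-0.05 Hz),
  a 1 g gravity offset on the z accelerometer, and maternal-motion
  artifacts at `maternal_artifact_rate` per minute. Artifacts are smooth,
  high-amplitude excursions (5-15 x noise, 3-8 s, modulated below
  0.4 Hz) plus occasional posture-shift steps that ramp in over about
  1.5 s. Both shapes keep their energy below the 1 Hz edge of the FM
  band; abrupt steps would otherwise leak broadband energy into it.
* **FM bursts** — 2-4 damped sinusoids with random frequencies in
  `fm_band_hz` (default 1-20 Hz) and random axis loadings; the gyroscope
  receives the same frequencies and envelope a quarter-cycle out of
  phase, emulating a rigid-body rotation-plus-translation event.
  `fm_snr_db` is defined at the *segment* level: a window carrying a
  burst holds about `10^(snr/10)` times the in-band energy of the bare
  background window. 12 dB (default) models clearly perceptible
  movements, 6 dB is still easy for a spectral classifier, and around
  3 dB (twice the background energy) the task becomes genuinely
  moderate. This window-level definition makes the generator's
  difficulty directly interpretable for a 5 s-window classifier: a
  simple 1-20 Hz band-power threshold reaches F1 about 0.97 at 6 dB,
  comfortably above the 0.8 floor the generator contract guarantees, so
  failures downstream indicate model problems, not an impossible task.
* **Annotation noise** — presses follow burst onsets with a Gaussian
  delay (mean 0.8 s, sd 0.4 s, clamped to [0, 2] s); spurious presses
  and unpaired confirmations are injected at configurable rates and
  placed at least two windows away from any press-bearing window, so
  dual confirmation stays exact. Unpaired confirmations carry a burst
  8 dB weaker than `fm_snr_db` — movements the mother does not feel are
  plausibly weaker — which keeps the N-FM class heterogeneous.

What the generator does **not** emulate: fetal heart activity, real
inter-subject transfer functions of the abdominal wall, sensor
saturation and temperature drift, or long-range nonstationarity of
maternal behaviour. Tests passing on this cohort therefore demonstrate
that the pipeline's arithmetic, label plumbing and learning dynamics are
correct — not that the trained networks would reach the same absolute
accuracy on clinical data.

## Segmentation, splitting and class balancing

`segment_and_label()` cuts `floor(duration / 5 s)` windows and applies
dual confirmation with a 2.0 s coincidence tolerance (the perception
delay model never exceeds it) and a minimum window/interval overlap of
0.5 s to avoid boundary flicker. `split_subject_independent()` assigns
whole subjects: 20% to test, then 20% of the remainder to validation
(`round`, at least one subject each); a registered fold map is applied
verbatim and validated for leakage, and every split asserts that the
subject sets are pairwise disjoint.

The FM minority is expanded by **virtual rotation**: each copy applies a
fresh unit quaternion to both sensor triples, re-expressing the signals
as if the patch had been worn in a slightly different orientation.
Quaternions follow the Hamilton convention, and conjugation uses the
inverse-on-left (passive) form `v' = q^-1 (0, v) q`; per-axis angles are
uniform on +/-15 degrees and composed intrinsically x, then y, then z
(the composition order is a documented choice; any fixed order gives the
same distributional guarantees). The expansion factor counts the
originals, so a factor of 10 takes 686 FM training segments to 6860.
Rotation happens in the time domain, before the STFT: the conjugation
acts on sensor vectors, which no longer exist once the spectrogram is
taken.

The N-FM majority is reduced by **adaptive k-means undersampling** in
the feature space of flattened, globally standardized log-spectrograms
(the same representation the classifiers see). The registered setting is
k = 12, at most 300 Lloyd iterations, tolerance 1e-4, with assignment by
a composite metric: `0.7 * L1/d + 0.3 * (1 - cosine)`; the L1 term is
normalized by the dimensionality so both terms share scale, and cosine
with a zero vector is defined as similarity 0. Selection is stratified:
per-cluster quotas by largest-remainder apportionment, and inside each
cluster picks alternate between the sample closest to the centroid in
Manhattan distance (centrality) and the sample minimizing the maximum
cosine similarity to the already-picked set (diversity). An optional
silhouette search over k in 4..24 (`adaptive = TRUE`) is off by default.

One numerical subtlety deserves emphasis. The within-cluster sum of
squared errors (WCSS) is a squared-Euclidean objective, and the
classical iteration that provably descends it assigns by squared
Euclidean distance. Assigning by the composite metric while updating
centroids as means forfeits that guarantee: on random data the WCSS
trace rises occasionally (we observed increases up to ~1.4% in about a
third of random datasets). `kmeans_fit()` therefore exposes
`metric = "euclidean"` — the exact WCSS-descending iteration, for which
the descent property is asserted in the test suite — alongside the
default `metric = "composite"` used by the undersampler. Empty clusters
are re-seeded at the sample farthest from its centroid; assignment ties
break toward the lowest cluster index.

## Spectrogram features

Six channels are merged to three: for each spatial axis, the merged
series is `zscore(accel) + zscore(gyro)`, computed per segment.
Z-scoring first puts the two sensors (different physical units) on a
common scale; summing per axis preserves directionality and keeps the
3-channel image shape; a zero-variance channel contributes a zero
series. Each merged channel passes through an STFT with a 256-sample
Hamming window and 50% overlap — no padding or centering, the last
partial frame dropped — giving a bit-reproducible 129 x 6 geometry for
950-sample segments; magnitudes become decibels via
`20 log10(|X| + 1e-8)`. Per-segment z-scoring happens on the raw series
(inside the merge), and a single global mean/sd pair fitted on the
training spectrograms standardizes all splits; the statistics object is
immutable and is never refitted downstream, which the tests assert as a
leakage guard.

## Classifiers and knowledge distillation

Four convolutional families operate on the 3 x 129 x 6 input
(channels x frequency x time), built on a small NHWC engine with
compiled im2col/depthwise kernels. Convolution matrix products (and the
undersampler's selection-stage similarity updates) run in single
precision — the standard working precision for CNN training — while
parameters, optimizer state and losses stay in double precision:

* preset 1 — inverted-residual student (pointwise expand, depthwise 3x3,
  linear projection; skip when shapes match), 0.32 M parameters;
* preset 2 — channel-shuffle student (grouped pointwise convolutions,
  shuffle, depthwise), 0.31 M;
* preset 3 — fire-module student (1x1 squeeze, mixed 1x1/3x3 expand),
  0.27 M;
* teacher — a plain residual network, 1.23 M parameters, trained from
  scratch. At desk scale a reduced teacher stands in for large
  pretrained backbones; the distillation mechanism is agnostic to the
  teacher's provenance.

Students downsample the frequency axis with stride 2 per stage and keep
the 6-frame time axis until the last stage. Parameter counts are exact
(318,050 / 309,018 / 271,034) and sit within 2% of the registered
budgets; widths are adjustable through a multiplier (rounded to
multiples of 4).

Training minimizes the distillation objective
`(1 - alpha) * H(y, s(zs)) + alpha * T^2 * KL(s(zt, T) || s(zs, T))`
with Adam (beta1 = 0.9, beta2 = 0.999, no weight decay); the hard-label
term uses the student's T = 1 output, the soft term temperature-softens
both logit sets, and the `T^2` factor keeps soft-gradient magnitudes
comparable across temperatures. Without a teacher the loss reduces to
plain cross-entropy, and `alpha = 0` with a teacher reproduces the
teacher-free trajectory exactly under the same seed (asserted in the
tests). Early stopping watches the validation value of the training
objective (the composite loss when distilling), restores the best
weights, and `patience = 0` stops one epoch past the first
non-improvement. Dropout sits before the final classifier at the
grid-searched rate; batch order and initialization are seeded, so every
fit is reproducible. The full search grid is temperature {1,3,5,7,9},
alpha {0.3,0.5,0.7}, learning rate {1e-4, 1e-3}, batch {16,32,64},
dropout {0.2,0.3,0.5}; `grid_search()` enumerates it exhaustively and
selects by mean validation F1 with ties toward smaller T, then smaller
alpha.

## Quantization and deployment accounting

`calibrate_and_quantize()` emulates full-integer INT8 post-training
quantization in software (fake quantization): per-output-channel
symmetric weight scales `max|w|/127` (zero point 0, round-half-to-even,
clamp to [-127, 127]), per-tensor biases, and per-tensor asymmetric
activation ranges observed over calibration batches, with the range
always containing zero. The quantized forward pass
quantizes/dequantizes at every layer boundary and is bit-reproducible
given the calibration set. Payload accounting: float32 = 4 bytes per
parameter; int8 = 1 byte per parameter + 4 bytes per quantization scale;
MB means 2^20 bytes. For the 0.32 M student this gives a ~1.21 MB float
payload and a ~74% reduction after INT8. On-device execution is out of
scope; the accounting and accuracy-preservation checks are the
deliverable.

Battery life uses a duty-cycle model: average power =
`(idle * t_acq + peak * t_inf) / (t_acq + t_inf)` with the measured-style
profile 135 mW idle, 179.8 mW peak, 5 s acquisition, 0.63 s inference,
3.7 V; hours = `derate * capacity / (power / voltage)`. With defaults a
1000 mAh cell yields about 26.4 h — linear in capacity and derate,
strictly decreasing in either power level.

## The desk-scale benchmark

`fm_benchmark_data()` is the registered end-to-end exercise: 24 subjects
x 140 windows at 3 dB (moderate), FM prevalence 0.12, subject-independent
split, FM augmented and trimmed to 1000, N-FM undersampled to 1000 —
2000 balanced training segments. `fm_benchmark_config()` freezes the
training settings: Adam 1e-3, batch 64, dropout 0.2, at most 8 epochs
with patience 2 (the synthetic task plateaus within a handful of
epochs), distillation at T = 3, alpha = 0.5, three repeat seeds. The
acceptance suite trains the 0.32 M student with and without a trained
teacher under these settings and asserts the distilled mean validation
F1 is at least the plain one, and that INT8 quantization costs at most
3 F1 percentage points on the test split. These problem sizes are the
package's desk-scale defaults; the same functions run the full fixture
when given it.

## Known limitations

* The CNN engine is CPU-only, double-precision and deliberately small;
  it is built for correctness and desk-scale reproducibility, not for
  large-scale training.
* The generator's waveform families are simple parametric stand-ins;
  absolute classification metrics on it do not transfer to clinical
  data.
* The composite-metric clustering has no monotone-objective guarantee
  (see above); it is used for what it is in this pipeline — a
  representative-selection heuristic.
* Quantization is emulated (fake-quant); integer kernel arithmetic on a
  microcontroller may round slightly differently.
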