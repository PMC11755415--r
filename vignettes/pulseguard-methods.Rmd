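---
title: "Cuffless blood-pressure estimation and anomaly detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuffless blood-pressure estimation and anomaly detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseguard)
```

## The problem

Arterial blood pressure (BP) is conventionally measured with an inflatable
cuff, which interrupts the patient and cannot run continuously. Cuffless
estimation instead predicts systolic (SBP) and diastolic (DBP) pressure from
optically and electrically measured surrogates: the photoplethysmogram (PPG),
whose pulse morphology is mechanically coupled to the arterial pressure wave,
and the electrocardiogram (ECG), whose R-peak timing relative to the pulse
arrival (pulse transit time, PTT) shortens as pressure rises.

`pulseguard` implements a complete, self-contained stack for this problem:

1. a seeded simulator producing synchronized PPG/ECG/ABP records with
   per-beat SBP/DBP ground truth;
2. five neural sequence-regression architectures (fully connected, LSTM,
   WaveNet-style dilated convolutions, WaveNet-LSTM, ResNet-LSTM) with three
   heads — direct SBP/DBP regression, entire-waveform regression, and a
   softmax hypertension-stage classifier — trained by the package's own
   gradient engine;
3. leave-one-subject-out (LOO) evaluation with MAE/RMSE reporting;
4. an analytic FLOPs cost estimator;
5. a distance-based anomaly detector built on a model of normality (MoN);
6. heart-rate zone analytics for wearable CSV exports.

## The synthetic cardiovascular simulator

Real waveform corpora for this task live in access-controlled clinical
databases. The simulator stands in for them so that every stage of the
pipeline is exercisable and testable offline. It emulates, per subject:

* **ABP**: quasi-periodic beats at a subject-specific heart rate (default
  55–95 bpm). Each beat is a two-Gaussian template — a systolic peak and a
  dicrotic bump on a diastolic baseline — min–max normalised per beat so the
  sampled waveform attains exactly the drawn per-beat SBP peak and DBP
  trough. Per-beat pressures follow a subject baseline plus a slow sinusoidal
  drift (default ±8 mmHg systolic).
* **PPG**: the ABP min–max normalised over the record, smoothed with a 50 ms
  moving average, plus additive Gaussian noise (`noise_sd`). Record-level
  normalisation reflects the fact that PPG amplitude is not calibrated to
  absolute pressure.
* **ECG**: a Gaussian R-wave (~20 ms wide) preceding each pulse foot by a lag
  that decreases linearly with the beat's mean arterial pressure — the
  inverse PTT relation.

**The morphology coupling.** `coupling_strength` in [0, 1] controls how
strongly waveform shape encodes the underlying pressures. The two cues are
expressed in absolute time rather than beat phase so they remain
identifiable across heart rates: the systolic peak width (in seconds) grows
monotonically with the systolic level, and the dicrotic bump's relative
amplitude falls with the diastolic level. At `coupling_strength = 0` the
template is pressure-independent and the inputs carry no BP information
(across subjects); at 1 with no noise the shape determines the pressures.
These are deliberate identifiability choices, not a hemodynamic model: the
simulator makes no claim of physiological validity, contains no arrhythmia,
motion artifact, or sensor drift, and its subjects differ only in heart
rate, baseline pressures and noise realisation. Passing tests on it
demonstrate that the estimation machinery works when the assumed
morphology–pressure coupling holds; they say nothing about performance on
clinical data, where the coupling is weaker, confounded and non-stationary.

**Windowing.** `make_dataset()` slides fixed-length windows (default 4 s,
2 s stride) and snaps each window start back to the latest beat onset at or
before it, so windows begin at a pulse foot. Beat intervals are half-open
`[onset_k, onset_{k+1})`; the trailing partial beat is dropped. Each window's
regression label is the mean of the per-beat values whose onsets fall inside
it.

## Network primitives and architectures

The primitives are implemented directly from their defining equations:
convolution as cross-correlation (the deep-learning convention), ReLU
thresholding at zero, 2×2 max pooling, the LSTM gate recurrences, the
residual mapping `H(x) = F(x) + x`, and max-subtracted softmax. Each is
pinned by tests to an independently coded scalar-loop reference.

Two description-level ambiguities were resolved as follows:

* Some published LSTM descriptions print the candidate transform with the
  input gate's parameters. Standard LSTMs use distinct candidate parameters;
  the package defaults to distinct `W_c`, `b_c` and offers
  `tie_candidate_to_input_gate = TRUE` to reproduce the literal tied form.
* The residual mapping is implemented in its canonical skip-connection form,
  with an explicit 1×1 projection on the skip path when widths differ; the
  projection is deliberately not counted as a convolutional layer.

**The ResNet-LSTM hybrid** follows the 20-layer layout: five convolutional
blocks holding 12 convolutions in a (3, 3, 2, 2, 2) split (3-wide kernels,
ReLU, one residual skip per block), each block closed by a 2-wide max pool
and a dropout layer (default rate 0.25), then one LSTM layer, one fully
connected layer, and the output head. The published description leaves the
2–3 convolutions-per-block split ambiguous; (3, 3, 2, 2, 2) is fixed here
and introspectable via `model_summary()`. The LSTM feeds all of its hidden
states (not only the last) to the FC layer: with only a handful of
time steps left after five pools, the last-state bottleneck measurably hurt
held-out-subject accuracy because the tanh-bounded state saturates for
subjects at the edge of the training pressure range.

**WaveNet families** are stacks of dilated causal 1-D convolutions with
dilation doubling per layer (1, 2, 4, …), ReLU activations and residual
sums — a deliberate simplification without gated tanh/sigmoid units, which
the source description does not specify. The entire-waveform head of the
pure WaveNet is a length-preserving 1×1 convolution; the other families map
their feature vector to the window length through a dense layer.

**Width scaling.** Layer widths scale with the number of input channels: a
PPG+ECG model doubles its conv channels and LSTM hidden size relative to the
PPG-only model. Under this convention the forward cost of the two-channel
model is ≈4× the single-channel one (cost is quadratic in width), matching
the complexity module's channel-doubling pattern.

**Hypertension stages** for the classifier head follow the standard clinical
systolic bands: normal < 120, elevated 120–129, stage 1 130–139, stage 2
≥ 140 mmHg.

## Training

No deep-learning framework is used: every layer implements an analytic
backward pass (im2col GEMM for convolutions — the one compiled kernel in the
package — max-routing for pools, BPTT for the LSTM), verified against
central finite differences in the test suite. Training minimises MSE on
z-scored targets (softmax cross-entropy for the stage head) with Adam,
batch shuffling, a step learning-rate decay (halved at 50% and 75% of the
epoch budget), and early stopping on a 10% validation split of the training
windows with best-parameter restoration. Inputs are centred per channel and
scaled by their maximum absolute deviation rather than the standard
deviation: the ECG is spike-like, and sd-scaling inflates its spikes to
several times the PPG's dynamic range, which destabilised two-channel
training.

One augmentation is applied (and can be disabled): a random circular time
shift of each training window per epoch. Beat-aligned windows are
near-periodic, so a circular shift yields another plausible window with the
same labels; without it the networks memorise absolute beat positions of the
training subjects and generalise poorly across subjects.

All randomness — initialisation, shuffling, dropout, the validation split,
augmentation — derives from the configured seeds, so runs are reproducible
on a given platform. Exact cross-platform bit equality is not promised
(BLAS summation order differs); tests therefore assert thresholds, not bit
equality, for trained results.

## Evaluation protocol

`loo_evaluate()` implements leave-one-subject-out cross-validation: P
subjects yield exactly P folds, each training on P−1 subjects and testing on
the held-out one. Direct mode scores the head's SBP/DBP outputs against the
window labels; entire mode scores the predicted waveform (MAE/RMSE) and
additionally derives SBP/DBP from the predicted waveform via per-beat
max/min extraction before scoring. Fold metrics are aggregated by
sample-count-weighted mean. Reports expose the conventional column layout
(`RMSE, MAE, MAE D, MAE S, RMSE D, RMSE S`), with waveform columns absent in
direct mode.

### The desk-scale benchmark

`benchmark_config()` fixes the package's reference evaluation: 12 subjects,
60 s records, full coupling, `noise_sd = 0.05`, simulator seed 7, sampled at
50 Hz with 4 s windows and 2 s stride (≈29 windows per subject), and a
hidden size of 8 with dropout 0 for the trained hybrid. The problem sizes
were chosen once so that a full 12-fold LOO run of the ResNet-LSTM completes
in a few minutes on one CPU; the 50 Hz rate halves compute relative to the
125 Hz simulator default while leaving all morphology cues resolvable.
Dropout is disabled in the benchmark because these reduced-width networks
underfit rather than overfit — with 0.25 dropout in five consecutive blocks
the optimiser cannot escape the mean prediction at this scale. The
architecture default remains 0.25, matching the reference layout.

On this benchmark the trained hybrid's leave-one-subject-out systolic MAE
improves on both the flattened-window linear baseline and the training-mean
predictor by well over 30% across training seeds. Input-channel
configurations are compared on the validation split (`validation_mae()`),
where adding the ECG channel lowers systolic MAE — the improvement direction
reported for full-scale clinical experiments. The two comparisons are
deliberately different: leave-one-out measures transfer to unseen subjects,
where at 12 subjects the wider two-channel network is noisier fold to fold,
while the validation comparison measures what the extra channel contributes
in distribution, which is the stable quantity at this cohort size.

## Complexity accounting

`estimate_cost()` pins the order-level costs: `L·V²` for the purely
feed-forward families and `L·V²·k` for the convolutional ones, so doubling
the representation width multiplies cost by exactly 4 — the mechanism behind
the ≈4× two-channel-vs-one-channel cost pattern. `count_model_cost()` walks
a built model and sums exact per-layer multiply-accumulates (1 MAC = 1 FLOP
by the package's documented convention; some texts count 2). Absolute
published FLOPs figures depend on unpublished layer sizes and are not
reproduction targets; the order and the 4× ratio are.

## The anomaly detector

The model of normality is the arithmetic mean of N normal feature
embeddings; a test embedding is scored by Euclidean distance to it and
flagged anomalous iff the score strictly exceeds the working-point
threshold (a score exactly at the threshold is normal). Thresholds follow
six rules over two calibration score vectors: `T1 = max(K1)`,
`T2 = max(K1) − std(K1)`, `T3 = mean(K1) + std(K1)`, and `T4–T6` likewise on
`K2`, with `std` the population (divide-by-n) standard deviation.

The source description never defines how `K1` and `K2` arise. The package's
reading: the feature extractor emits a feature map, pooled two ways —
max-pooled and mean-pooled — giving two embedding variants; scoring a
held-out normal calibration split under each pooling yields `K1` and `K2`
respectively, and classification uses the pooling variant matching the
chosen rule. The normals used to build the MoN and those used to calibrate
the threshold are disjoint halves of the normal set: whether the original
procedure reused one set for both is unstated, and separating them avoids
the optimistic bias of calibrating on the MoN's own training points.

The bundled extractor is a seeded random tanh projection so the detector
runs without any pretrained network; any callable mapping an input to a
feature map can replace it (a pretrained image backbone, a trained
`bp_model`'s intermediate layers, …).

## Heart-rate analytics

Zone minutes attribute each inter-sample interval to the zone of its leading
sample, so per-zone minutes conserve the total duration exactly under
irregular sampling. Default zone boundaries follow the conventional
percent-of-max-HR bands (50/70/85% of 220 − age, age 40) purely as an
overridable placeholder — device vendors use proprietary boundaries.
Quartiles use linear-interpolation (type-7) quantiles; outliers are Tukey's
1.5·IQR fences. Correlation matrices are Pearson, with an explicit error
naming any constant channel.

## Numerical and degenerate-input choices

* Degenerate pressure ranges (min = max) give coupling level 0 rather than
  0/0.
* `extract_sbp_dbp` requires ≥2 onsets; the trailing partial beat is
  dropped. Entire-mode evaluation falls back to whole-window max/min when
  fewer than two onsets fall inside a window.
* The least-squares baseline returns the minimum-norm solution with a
  warning on rank-deficient designs.
* Softmax subtracts the maximum before exponentiation; sigmoid/tanh use the
  stable library forms.
* A non-finite training loss raises a divergence error naming the epoch.
* Zero training epochs return the input model unchanged; a zero learning
  rate provably leaves parameters untouched.

## Known limitations

* The simulator is an identifiability scaffold, not physiology; results on
  it bound nothing about clinical data.
* Sequence training is CPU-bound R + one small compiled kernel: fine at
  benchmark scale, not intended for hour-long records or hundreds of
  subjects.
* Cross-platform bit determinism of trained weights is not guaranteed.
* WFDB support covers single-segment format-16 records only, and heart-rate
  CSV parsing targets the common timestamp/value export layout.
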