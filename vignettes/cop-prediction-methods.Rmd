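---
title: "Predicting the stance-phase COP trajectory from wearable IMUs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the stance-phase COP trajectory from wearable IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The center of pressure (COP) — the point of application of the resultant
ground reaction force under the foot — traces a characteristic heel-to-toe
path during every stance phase of walking, and its trajectory carries
clinically useful information about balance. Measuring it directly requires
force plates or pressure insoles, which are expensive, spatially
constrained, or short-lived. Body-worn inertial measurement units (IMUs)
are cheap and unobtrusive; `copgait` implements a pipeline that learns to
predict the stance-phase COP trajectory from IMU signals alone, and
evaluates which sensor placements — heel (H), lateral shoe wall (L), toe
(T), waist (W), and every combination of them — carry the most predictive
information.

## Pipeline overview

1. **Synchronization** (`synchronize`). Recording starts with a floor
   stomp. The first prominent peak of the heel accelerometer magnitude and
   of the vertical GRF mark the same physical event; all sensor streams
   are shifted so the two peaks coincide.
2. **Swing-noise cleaning** (`clean_swing_noise`). Plantar pressure must
   be zero while the foot is airborne; any vertical GRF below 10 N is
   treated as mat noise, zeroed, and its COP set to the swing sentinel
   (`NA` — never zero, so downstream code must mask stance explicitly).
3. **Gait events** (`detect_gait_events`). Heel strike is the first frame
   of a contact epoch at which GRF reaches 10 N; toe off is the first
   frame after the epoch's force maximum at which GRF drops below 25 N.
   The thresholds are standard for force-based event detection; the
   crossing directions (rising for heel strike, falling after the peak for
   toe off) match loading and push-off physiology. Epochs shorter than
   0.3 s are rejected as artifacts, which also removes the stomp itself.
4. **Windowing** (`build_samples`). Prediction is many-to-one: the model
   sees a lookback window of `P` frames of stacked IMU channels ending
   immediately *before* the target frame, and predicts the COP at that
   frame; the window then advances frame by frame through the stance.
   `P` is the participant's mean heel-strike-to-heel-strike cycle length
   over the *training* steps (`mean_step_period`), so each window spans
   roughly the preceding swing plus the stance so far. Windows that would
   reach before the start of the recording are skipped, not zero-padded —
   edge steps are unrepresentative anyway and are typically trimmed.
5. **Regression** (`train_copnet`). A three-layer LSTM (64/128/64 units)
   with a dropout layer before the linear read-out, trained with an RMSE
   loss and RMSprop for 20 epochs at batch size 148 (one second of frames
   at the nominal rate). One independent single-output model is trained
   per COP direction (anterior-posterior, AP; medial-lateral, ML).
6. **Evaluation** (`nrmse`, `jaccard_index`). Per test step: the
   root-mean-square error normalized by the measured curve's range
   (percent), and an area-based Jaccard similarity — both curves shifted
   so their origins are zero, then the trapezoidal area under the
   pointwise minimum divided by the area under the pointwise maximum.
7. **Placement sweep** (`run_sweep`). All 15 non-empty subsets of
   {H, L, T, W} are trained and evaluated per direction on one shared
   train/test split, so placement effects are compared on identical steps.

## The synthetic data generator

No public recording accompanies this class of experiment, so the package
ships a first-class simulator (`generate_session`) whose defaults *are*
the study conditions: 148 Hz sampling, 74 analysed left-foot steps per
session, stance length drawn from N(120, 6²) frames inside a 163-frame
(~1.1 s) cycle, body weight 541 N, an AP COP path of 17.48 cm, an ML
excursion of 1.48 cm, a double-bump vertical GRF, a single stomp spike
before the first step, and a uniformly drawn −30..30-frame lag between the
sensor and plantar clocks to exercise synchronization.

Design choices worth recording:

* **Phenomenological IMU waveforms.** Each channel is a fixed sum of
  phase-locked Gaussian bumps and low-order sinusoids of the latent gait
  phase, not rigid-body physics. What the pipeline needs from the
  generator is (a) site-specific activity *timing* — heel quiet between
  foot-flat and heel-off, lateral quiet in mid-stance, toe dynamic through
  the entire stance, waist low-amplitude and smooth — and (b) a learnable
  deterministic IMU-to-COP coupling. Both IMU and COP waveforms are
  functions of the same latent phase multiplied by one per-step amplitude
  jitter (SD 0.05), plus per-channel white noise (SD 0.05 of the channel
  amplitude), so within-subject variability is present but the mapping
  remains identifiable.
* **GRF shape.** The double-bump stance profile rides on a 12 %-of-peak
  plateau so the first and last stance frames sit well above the 10 N and
  25 N event thresholds. Consequence: the detected stance equals the
  generated support exactly at any IMU noise level, which is what makes
  ground-truth event comparison a meaningful oracle test rather than an
  approximate one. Loading at 148 Hz is one frame (~7 ms), consistent with
  the fast loading transient of real heel strikes.
* **ML COP** is a single smooth lateral arc of calibrated excursion; only
  the excursion magnitude is calibrated, not the arc's shape.
* **Swing COP is `NA`**, a sentinel rather than zero, to force explicit
  stance masking downstream.
* **The stomp** is a half-sine of width 0.05 s with height three times the
  normal gait peak in both the GRF and the heel accelerometer; only its
  first-peak position matters for synchronization. It is placed far enough
  into the pre-gait segment that the largest negative lag cannot clip it.
* **Units.** Accelerations are in g and angular rates in deg/s, a common
  IMU export convention; no claim of fidelity to a particular instrument
  is made.

What the generator does *not* emulate: between-subject covariate
structure, fatigue or speed drift across a session, pressure-grid images
(COP is emitted directly; `compute_cop_centroid` provides the standard
pressure-weighted centroid for users who do have raw grids), right-foot
streams, or magnetometer channels. Tests passing on this generator
therefore demonstrate that the pipeline's machinery is correct and that
the model can exploit a deterministic phase coupling at realistic noise —
they do not certify accuracy on any real population.

## The regressor

The LSTM is implemented in the package itself (single-precision
RcppArmadillo with batched BLAS and full backpropagation through time)
rather than through an external deep-learning framework. Numerical
choices:

* **Architecture**: stacked LSTM layers of 64, 128 and 64 units, inverted
  dropout (rate 0.2) on the final hidden state, a single linear output
  unit. Gate order i/f/g/o, Glorot-uniform weight init, forget-gate bias
  initialized to 1.
* **Loss and optimizer**: RMSE loss (gradient `(p - y) / (B * RMSE)`),
  RMSprop with learning rate 1e-3, rho 0.9, epsilon 1e-8. Dropout rate
  and learning rate are conventional defaults, recorded in
  `model_config` and overridable.
* **Target scaling**: targets are z-scored inside `train_copnet` (the
  statistics live in the model and are inverted at prediction). The AP
  axis spans ~17 cm; without target scaling a 1e-3-rate optimizer cannot
  traverse that output scale in 20 epochs, and the loss would be
  dominated by the output bias. Input channels are z-scored with
  *training-set* statistics via `standardize_samples` — accelerometer (g)
  and gyroscope (deg/s) channels differ by two orders of magnitude, so
  mixed-unit inputs need it.
* **Batching**: shuffled mini-batches of 148 samples; the sample order,
  weight init and dropout masks all draw from R's RNG, so a fixed
  `model_config(seed =)` reproduces training bitwise on one machine.
* **Gate activations** use a clamped Padé(7,6) rational `tanh`
  (~1e-7 absolute accuracy), a standard fast-math choice; elementwise
  activations are the dominant non-BLAS cost at this model size.
* **Causality**: windows end strictly before the predicted frame, so the
  frame-by-frame rollout never sees the future; a perturbation test
  asserts this.

## Evaluation details

* **NRMSE** uses the pair's actual sample count and normalizes by the
  *measured* curve's range per step. It is invariant under a common
  affine rescaling of both curves.
* **Jaccard**: after origin alignment, both curves are offset together by
  their common minimum so areas are well-defined even when an ML curve
  goes negative; the common offset preserves the inter-curve geometry.
  Integration is trapezoidal on the shared uniform frame grid (the
  integration scheme is a free choice; equivalence with a 10x-oversampled
  trapezoid on smooth curves is asserted to 1e-6 in the tests). Two
  identically-zero curves return 1 by convention. Predicted and measured
  curves have equal length by construction here; time-warped comparison
  of unequal-length curves is out of scope.
* **Aggregation** reports mean and sample SD per combination and
  direction, ordered by subset size then lexical site order; a
  single-step group reports SD 0 with n = 1.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run at the study's own scale
where the claim depends on it, and at reduced scale where only plumbing is
exercised: generator calibration uses 222–300 default steps (estimates of
the calibrated means are then compared within two standard errors); the
end-to-end single-sensor check trains the full 64/128/64 model on one
74-step subject (~6,200 windows of 163 frames) for the full 20 epochs; the
sweep and unit tests use short 50 Hz sessions with 30-frame cycles, which
leave every code path identical while keeping the matrices small. The
70/30 split of 74 steps gives 52 training and 22 test steps.

## Known limitations

* The simulator's phase coupling is cleaner than real gait: real IMU-COP
  relationships drift with speed, footwear and fatigue, and real ML COP
  prediction is much harder than AP (the ML excursion is an order of
  magnitude smaller than the AP path, so the same absolute error costs
  far more normalized error). Expect the ML metrics on synthetic data to
  be optimistic relative to any real recording.
* One model is trained per subject, per combination and per direction;
  pooling subjects is expressible (concatenate sessions) but not the
  default, mirroring per-participant lookback computation.
* Training is CPU-oriented; no GPU path is provided.
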