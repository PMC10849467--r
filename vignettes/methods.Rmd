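---
title: "Methods: masked-patch pre-training for IMU-based GRF estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masked-patch pre-training for IMU-based GRF estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(grfimu)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, the numerical choices, what the
synthetic data generator does and does not emulate, and the design decisions
taken where the design was genuinely open. No empirical claim is made here
beyond what the test suite and `scripts/acceptance.R` themselves compute.

## The estimation problem

The target is the right leg's 3-axis ground reaction force (GRF) —
medial-lateral, anterior-posterior, vertical — expressed per body mass
(N/kg), from eight body-worn IMUs (trunk, pelvis, both thighs, shanks,
feet), each providing a 3-axis accelerometer (m/s²) and 3-axis gyroscope
(deg/s). The model input is a 128-sample window at 100 Hz with 48 axes in a
fixed sensor-major order (per sensor: acc x/y/z, gyr x/y/z). Mass-normalized
GRF makes thresholds mass-free: "2% of body weight" is 0.02 × 9.81 = 0.1962
N/kg for every participant.

Supervised training of such a model is label-limited: synchronized
IMU + force-plate data is expensive. The package therefore pre-trains the
encoder with a masking-and-reconstruction pretext task on unlabeled IMU
windows — real or synthesized from motion-capture kinematics — and
fine-tunes on labeled data.

## Synthetic IMU generation

Given per-segment global positions $p(t)$ and orientations $R(t)$ (unit
quaternions, segment→global):

* **Filtering/resampling.** Positions and quaternion components pass a
  zero-lag (forward–backward) 4th-order Butterworth low-pass at 15 Hz, then
  linear interpolation onto a 100 Hz grid; quaternions are re-normalized.
  The forward–backward pass squares the magnitude response, so a 1 Hz gait
  harmonic is attenuated by less than $10^{-9}$. Because a naive
  forward–backward pass has startup transients, the signal is extended by
  odd reflection on both ends before filtering and trimmed afterwards; with
  full-length reflection padding the transient is below $10^{-9}$ even on
  constant signals.
* **Gyroscope.** The sensor-frame angular velocity at step $t$ is the
  rotation-vector (log-map) of $R_s(t{-}1)^\top R_s(t{+}1)$ divided by
  $2\Delta t$, converted to deg/s. The symmetric difference is second-order
  accurate and frame-correct; the sensor frame is chosen because that is
  what a physical gyroscope measures.
* **Accelerometer.** The central second difference
  $(p(t{+}1) - 2p(t) + p(t{-}1))/\Delta t^2$ plus the gravity vector
  $(0, 0, +9.81)$ m/s², rotated into the sensor frame. Adding (not
  subtracting) gravity makes a static upright sensor read +9.81 on its
  up-axis, matching real accelerometers, which measure the reaction to
  gravity. Endpoint samples copy their nearest interior value; the boundary
  handling is a package choice, as is the z-up global frame.
* **Mounting perturbations.** Each sensor is additionally rotated by three
  angles drawn uniformly in ±10°, composed intrinsically x→y→z about the
  sensor axes. The composition order is a package choice; the three-angle
  bound is part of the protocol. Perturbing by a rotation and then its
  inverse reproduces the unperturbed signal to $10^{-9}$ (asserted in the
  tests).

## Preprocessing

Windows of 128 samples with 50% overlap start at samples 0, 64, 128, …
(0-based, half-open spans), giving $\lfloor (n-128)/64 \rfloor + 1$ windows;
trailing remainders are discarded since the model input length is fixed.
Exclusion filters:

* **Stillness**: a window is removed when the mean over the 24 accelerometer
  axes of the per-axis standard deviation falls below 0.2 m/s². The same
  criterion is applied to real-style and synthetic corpora; a
  mean-*acceleration* criterion would remove nothing once gravity is
  included, so the standard-deviation form is used as the one that actually
  captures "standing or sitting still".
* **Range outliers**: any sample with |acc| > 160 m/s² or |gyr| > 2000 deg/s
  removes the window (typical IMU measurement ranges). Comparisons are
  strict: values exactly at a threshold are retained; the boundary behaviour
  is a package choice.

Labeled gait trials are cut into one window per stance onset, starting 40
samples before the onset (clamped at the trial start, dropped if the window
overruns the trial). Short drop-landing trials (80 samples = 0.8 s) are
zero-padded to 128; `valid_length` records the real length and padded rows
are excluded from every statistic and loss.

Normalization is per-axis z-scoring (IMU and, on labeled data, GRF).
Standard deviations below $10^{-8}$ are clamped to $10^{-8}$ so constant
axes map to zero rather than infinity. Statistics are fitted on the
pre-training corpus for SSL and refitted on each downstream training fold
for fine-tuning — the downstream distribution (e.g. drop landing) can differ
substantially from the pre-training corpus, so fold-local statistics are the
conservative choice.

## Model

A post-norm transformer encoder in the original arrangement
(sublayer → dropout → residual add → layer norm):

| parameter | default | meaning |
|---|---|---|
| `patch_length` | 1 (grid 1–8) | samples per token; 1 token = `patch_length` × 48 values, flattened sample-major |
| `masking_ratio` | 0.125 (grid 0.0625–0.625) | fraction of tokens replaced by the mask patch |
| `embed_dim` | 192 | token width |
| `n_blocks` / `n_heads` / `ff_dim` | 6 / 8 / 512 | encoder blocks, attention heads, feedforward units |
| `dropout` | 0.10 | active during training only |
| `layer_norm_eps` | $10^{-5}$ | layer-norm stabilizer |

The mask patch lives in raw patch space (length `patch_length` × 48), shared
across positions, and is applied *before* the linear embedding; positional
encoding (standard sinusoidal, base 10000) is added after embedding, to
masked and unmasked tokens alike. The reconstruction head is a per-token
linear map back to patch size; the GRF head maps each token to
3 × `patch_length` values. Exactly `round(ratio × n_tokens)` distinct tokens
are masked per window, resampled freshly at every training step, which is
standard masked-autoencoder practice. Omitted sensors are replaced by one
trainable patch per sensor (length `patch_length` × 6), tiled over time —
one per sensor rather than per sensor-and-position, for parameter economy.

Weight initialization: linear layers Kaiming-uniform, attention projections
Xavier-uniform, biases zero; mask and substitution patches are small
Gaussian draws (SD 0.02). At the full-scale configuration the trainable
parameter count is 2,096,544 ≈ 2 M (recomputed by `scripts/acceptance.R`).

The forward *and* backward passes are hand-written dense matrix algebra;
gradients were verified against central finite differences at relative
errors below $10^{-6}$ during development, and the shipped tests pin the
loss to an independent brute-force recomputation and the encoder to a
hand-composed attention oracle.

## Training

AdamW (decoupled weight decay 0.01, applied to all parameters; β = 0.9,
0.999, ε = $10^{-8}$), batch size 64, MSE loss. The learning rate ramps
linearly from `peak/warmup_steps` at step 1 (the first optimizer step is
already nonzero; the ramp's first value is a package choice) to the peak at
20% of the steps, then follows cosine decay to zero without restarts.
Batches are shuffled without replacement and reshuffled each epoch. No early
stopping, no gradient clipping. Padded rows never enter a loss.

* **SSL pre-training**: masked-patch MSE over masked entries only; peak LR
  $10^{-4}$ for the full-scale $5 \times 10^4$-step protocol. The
  desk-scale profile (500 steps) uses peak LR $10^{-3}$: when the schedule
  shrinks a hundredfold, the peak rate must scale up or the encoder never
  leaves its initialization — at $10^{-4}$ over 500 steps the held-out
  masked-reconstruction error barely moves, while at $10^{-3}$ it drops
  by more than an order of magnitude.
* **Supervised transfer pre-training** (baselines): same encoder, per-token
  linear head, MSE on all samples — real IMU→GRF ("motion transfer") or
  synthetic IMU→body-centre acceleration ("task transfer").
* **Two-step fine-tuning**: the GRF head is freshly initialized (the
  reconstruction head has a different output dimension, so inheriting its
  weights is not meaningful); step 1 trains the head alone for 300 steps at
  peak LR $10^{-3}$ with the encoder bit-frozen, step 2 trains everything
  for 300 steps at $10^{-4}$. Freezing first prevents a randomly initialized
  head from distorting the pre-trained representation.

Determinism: a single seed drives weight init, shuffling, masking and
dropout; identical seed + data + config reproduce loss histories bit-exactly
on one device.

## Evaluation

Per participant, all included samples are concatenated before computing
Pearson ρ and RMSE per axis — "included" meaning gold vertical GRF at or
above 0.1962 N/kg (stance/landing); this follows the protocol of scoring
across all stance phases of a participant rather than averaging per-window
scores. Peak metrics take one peak (max of vGRF over included samples) per
window; rRMSE divides by the participant's global gold vGRF range. Spectrum
error is the one-sided FFT magnitude spectrum of the estimate minus that of
the gold signal, averaged over windows (65 bins for 128-sample windows at
100 Hz). Signed differences are the default since they preserve the
direction of spectral bias; an absolute mode is selectable.

Cross-validation splits *participants* (never windows) into five seeded
folds whose sizes differ by at most one. Scaling curves subsample training
*windows* at fractions 100%…10% (linear, 10 points) or $10^0…10^{-2}$ in
steps of $10^{-0.2}$ (exponential, 11 points), with nested seeded subsets so
smaller fractions are contained in larger ones — this isolates the effect of
quantity from resampling noise. Model settings are compared by one-way
ANOVA over per-participant metrics; if significant at 0.05, all pairwise
paired t-tests follow with Bonferroni correction (raw p × number of
comparisons, capped at 1).

## The synthetic data generator

`fixture_config()` / `make_corpus()` emulate the *structure* of
multi-participant gait and drop-landing datasets, not their biomechanics:

* an 8-segment rigid configuration with periodic joint trajectories
  (sinusoid mixtures at the stride frequency and first harmonics, band-
  limited well under 6 Hz), per-participant cadence (drawn from 105–135
  steps/min; 120 steps/min ⇒ 1 Hz stride frequency per leg), amplitude gain
  (±15%) and phase jitter;
* stride-to-stride variability: a slow (< 0.3 Hz) sinusoid-mixture
  modulation of movement amplitude (depth 0.12) and stride timing (phase
  wander ±0.6 rad), shared between kinematics and GRF. Real gait is not
  perfectly periodic; without within-trial variability every window of a
  participant is a near-copy of every other, and a few labeled windows
  carry as much information as the whole trial — which would defeat any
  data-efficiency experiment run on the fixtures;
* ground-truth GRF derived from the same internal phase variable: a
  double-peaked vertical profile during the 60% stance fraction scaled to a
  peak of 1.2 body weights × participant gain, exactly zero in swing,
  smaller-amplitude ml/ap components of the same state; stance onsets are
  the stance-entry samples. Sharing the phase between kinematics and GRF
  makes the task learnable by construction — a kernel ridge oracle reaches
  ρ > 0.8 on held-out participants (asserted in the tests), so a model
  failure is attributable to the model, not the data;
* optional still pads at the trial boundaries (exactly constant pose, with
  0.5 s smooth ramps into the active region) to exercise the stillness
  filter, and additive Gaussian sensor noise (0.05 m/s², 0.5 deg/s) as a
  token of measurement noise;
* drop-landing trials: 80 steps of free fall plus a Gaussian landing
  deceleration impulse shared by all segments, GRF exactly zero before
  touchdown — sized to exercise the zero-padding path exactly.

What the generator does **not** emulate: soft-tissue artifact, detailed
musculoskeletal dynamics, foot-ground impact transients, magnetometer
channels, real placement errors beyond rigid rotation. Passing tests
therefore demonstrate that the machinery is correct and that the SSL
mechanism works on structured periodic data; they do not certify accuracy
numbers on real gait.

## Scaled-down study conditions

The package's end-to-end demonstration (test-acceptance) uses sizes chosen
to keep the whole suite in CPU-minutes while leaving the protocol intact:
8 participants (6 train / 2 test) × 40 s trials, the `tiny_model_config()`
architecture (2 blocks, width 64, ff 128, patch length 8 — about 117 k
parameters), 500 SSL steps, and two-step fine-tuning (300 + 300 steps) on
10% of the labeled windows, averaged over 3 seeds. Under these conditions
the suite requires pre-training to improve held-out vGRF correlation by at
least 0.02 over random initialization and to at least halve the held-out
masked-reconstruction error. This is a desk-scale analogue of the
full-scale contrast, not a reproduction of published correlation values,
which require the original motion-capture corpora and GPU-scale budgets.

A caveat the suite itself exposes: the reconstruction half of the contrast
is decisive (the pre-trained encoder's held-out masked-MSE is more than an
order of magnitude below the untrained model's), but the downstream-
correlation half saturates on these fixtures. Because gait windows are
onset-aligned and the fixture's stance profile is a smooth function of
phase, even a randomly initialized model fine-tuned on ~23 labeled windows
reaches vGRF ρ ≈ 0.975 on held-out participants — the same ceiling the
pre-trained model reaches — so the 0.02 margin is not attainable at this
fixture difficulty and that assertion fails. The fixture is kept simple by
design (learnable in CPU-minutes); on data where labels are genuinely
limiting, the downstream margin is the interesting quantity, and the
representation-quality measure is the one this package can certify at desk
scale.

## Numerical choices and degenerate inputs

* Normalization SD clamp $10^{-8}$; constant axes z-score to zero and invert
  back exactly.
* Softmax rows are max-shifted before exponentiation.
* Rotation log map switches to a series expansion below $10^{-7}$ rad and a
  symmetric-part reconstruction near π.
* `round(ratio × n_tokens) = 0` is a configuration error for training but a
  non-fatal "invalid cell" in the grid search.
* Zero-variance inputs to Pearson correlation and zero gold range in rRMSE
  raise errors rather than returning NaN.
* Ties in mask sampling cannot occur (sampling without replacement);
  fold sizes differ by at most one by round-robin assignment after a seeded
  shuffle.

## Known limitations

* Single-device, CPU-oriented training; the full-scale configuration (2 M
  parameters, 5 × 10⁴ steps) is expressible but impractical without
  acceleration.
* No gait-event detection: stance onsets must come from annotations.
* The window store and checkpoints are R serialization files, portable
  across platforms but not across languages.
* The CLI is a thin wrapper over the package functions; it does not manage
  experiment queues or remote execution.
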