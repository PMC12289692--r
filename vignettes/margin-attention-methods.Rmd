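---
title: "Margin-optimized attention for motor-imagery EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin-optimized attention for motor-imagery EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the decoding model, the margin-optimized attention objective, what the
synthetic generator does and does not emulate, the numerical choices, and
the limitations we know about.

## 1. The decoding problem and the model

Binary motor-imagery decoding asks whether a 4-s EEG epoch follows a cue
to imagine a left-hand or a right-hand movement. The physiological marker
is event-related desynchronization: mu-band (8–12 Hz) power over the
sensorimotor cortex contralateral to the imagined hand drops relative to
the ipsilateral side. Everything in the pipeline exists to expose that
weak, lateralized band-power contrast to a classifier.

The backbone treats the EEG channels the way image networks treat RGB
planes: channels become the convolutional *depth*, kernels are `(1, k)`
along time only (`k` in 8/24/40), and the depth grows by the algebraic
progression `chans*k0, chans*(k0+1), ...` rather than geometrically. Each
layer halves the time axis (stride 2, zero "same"-style padding, so
`out = ceil(in/2)`). On the reference 64-channel configuration with a
180-sample window this yields the time progression 90, 45, 23, 12, 6, 3
and flattened sizes 11 520 down to 1 344 — versus 49 152 when the channel
axis is preserved as a spatial dimension, which is the computational
argument for the collapsed layout (`shape_trace()` reproduces this
arithmetic exactly, and the test suite pins it).

After the last convolution the time axis becomes the sequence axis of a
many-to-one bidirectional LSTM (the per-timestep feature vector is the
depth, 448 in the reference configuration instead of 16 384). An
attention layer pools the LSTM outputs; a small dense head with two
logits classifies. Batch normalization follows each convolution (before
the ReLU; the exact placement is a design choice we document rather than
inherit), and the head activation is selectable between ReLU and the
experimental odd, monotone function `|x| * tanh(x)`, which dampens small
inputs quadratically and grows like `|x|`.

## 2. Margin-optimized attention

Standard scaled dot-product attention scores keys by similarity to a
query. The layer implemented here replaces similarity scoring with an
affine margin score over encoder features `phi` (the keys):

`s_j = A . phi_j + b`

and trains `(A, b)` under the soft-margin SVM objective via the hinge
surrogate

`L_SVM = 1/2 ||A||^2 + C sum_i max(0, 1 - y_i (A . phi_i + b))`,

evaluated on the attention-pooled feature of each trial with the trial's
label. `L_SVM` joins the cross-entropy loss as
`total = CE + lambda_aux * L_SVM / batch` and its gradient flows through
`A`, `b` *and the encoder features* by ordinary backpropagation — no
quadratic-programming solver runs in the training loop. Design choices:

* **Normalization.** The raw margins are turned into a distribution over
  key positions by a softmax (clip-at-zero-and-renormalize is available
  behind a switch). Softmax preserves a proper weighting simplex while
  letting the margins order the keys.
* **Labels never touch the scoring path.** They enter only the auxiliary
  loss, so inference is label-free and the auxiliary term is exactly zero
  then.
* **Subgradient at the kink is 0**, matching `max(0, .)` autodiff
  convention.
* **Defaults** `C = 1`, `lambda_aux = 0.1`, both config-exposed. The sum-
  form objective is divided by the batch size in the total loss so that
  the effective auxiliary weight does not scale with the batch.
* **Per-head weights.** In multi-head settings each head gets its own
  `(A, b)`; the scoring is per-key, so all query rows of a trial share one
  weight distribution.

A property worth knowing (it shaped our tests): with *frozen* features,
training only the attention weights under the hinge does not by itself
increase the Fisher separation of the pooled contexts — concentrating the
pooling weights inflates the pooled-feature scatter roughly as fast as it
moves the class means apart. The separation gain appears when the hinge
gradient also reaches the feature projection, which is exactly how the
layer is used inside the networks. The corresponding test trains a
feature projection jointly with `(A, b)`.

The package also contains a standalone surrogate minimizer
(`fit_margin_params`): full-batch Adam on the exact hinge followed by a
BFGS polish on a softplus smoothing whose temperature is driven to 1e-6.
The polish exists because first-order steps oscillate in the last digits
around the hinge kinks; the homotopy ends within ~1e-6 of the optimum of
the exact objective (verified in the tests against an independent
interior-point solution of the SVM dual).

## 3. The synthetic generator: what it emulates, what it does not

`generate_recording()` builds, per subject, a continuous multichannel
record containing:

* **1/f background**: spectrally shaped white noise (`noise_exponent`,
  default 1), SD 2 µV;
* **cue-locked mu bursts**: a subject-specific 9–11 Hz oscillation
  (RMS 4 µV, random phase per channel) during each 4-s trial, with
  **ERD lateralization**: the contralateral channel group's mu power is
  multiplied by `erd_factor` (first half of the channels = left
  hemisphere = contralateral to right-hand imagery, label +1);
* **blinks**: 0.4-s half-cosine bumps at 10x the noise SD arriving at
  Poisson times (`blink_rate`/min) — spectrally below 4 Hz so the
  high-pass filter demonstrably suppresses them;
* **between-subject variability**: per-subject gain, mu frequency and
  amplitude jitter, per-channel gains, so that leave-one-subject-out
  generalization is a real task.

Defaults are the package's study conditions, chosen once: 8 subjects,
200 trials/subject, 8 channels, `erd_factor = 0.5`, and `fs = 90` Hz so
that a 4-s trial is 360 samples and maps onto the 180-sample model window
by exact factor-2 block averaging (the 180-sample window is the unique
even length whose six-fold ceiling-halving yields the reference 90…3 time
progression). The mu amplitude over the noise floor keeps the in-band
background bias of the contralateral/ipsilateral power ratio far below
the ±0.1 recovery tolerance asserted in the tests.

What the generator does **not** emulate: volume-conducted scalp
topographies (channel groups are a convention, not a forward model),
non-stationarities over a session, realistic artifact diversity (EMG,
line noise), or multi-class imagery. Passing tests on this generator
therefore demonstrates that the pipeline recovers a planted, physiologically
shaped band-power contrast under subject variability — not that it
matches any particular accuracy on real recordings.

## 4. Preprocessing

Fourth-order Butterworth high-pass at 4 Hz (ocular artifacts dominate
below 4 Hz), **no** low-pass. Filtering is zero-phase
(forward–backward) by default because offline cue-locked analysis should
not phase-shift the epochs; a single-pass causal mode exists and is what
the analytic gain checks use, since its magnitude matches the closed form
`|H(f)| = (f/fc)^n / sqrt(1 + (f/fc)^(2n))`.

Epochs are `[onset, onset + 4 s)`, half-open, 0-based; events whose
window exceeds the recording are dropped and counted. Artifact rejection
uses the per-unit mean absolute value with threshold `mean + 3 SD`
(strict inequality, so a zero-variance batch rejects nothing), applied in
a single pass — channels first, then trials. The channel/trial order is
a documented choice: the rejection prose names both targets without
fixing an order, and removing a saturated channel before scoring trials
prevents one bad electrode from condemning every trial.

## 5. Transformer variant

Epochs are cut into non-overlapping 45-sample crops (label inherited,
remainder dropped), linearly interpolated to 72 samples — the published
"resize to 72" is an image-resize phrase; for a time series we read it as
1-D linear interpolation per channel — then split into 72/8 = 9 patches
of all channels x 8 samples, each linearly projected with a learned
positional embedding (patch size is not stated anywhere we could find;
8 is the config-exposed default). Encoder blocks are pre-norm:
`t2 = x + Attn(LN1(x))`, `out = t2 + MLP(LN2(t2))`; the attention is
multi-head softmax or the margin layer, interchangeable behind one
config key. Training uses AdamW (lr 1e-3, weight decay 1e-2 — values the
source leaves unstated) with metric-based early stopping: best validation
metric initialized to negative infinity, stop after `patience`
non-improving epochs, restore the best checkpoint. Of the three metric
slots mentioned in the source ("profit", accuracy, loss) only accuracy
and loss are meaningful to us; the third slot is pluggable but unused.
With `ConvDOWN` enabled the channels-as-depth conv stack runs first and
its timesteps become the tokens.

## 6. Evaluation

LOSO folds: one per subject, deterministic order, with a label-stratified
15% of the training subjects' trials held out for early stopping. The
70/15/15 pooled split is used for the within-distribution baselines and
the ablation. Metrics: accuracy, sensitivity = TP/(TP+FN) for the +1
class, F1; ties in the logits break toward the negative class (documented
because it affects degenerate predictors). Class separation is the Fisher
criterion `J = ||mu_+ - mu_-||^2 / (tr(Sigma_+) + tr(Sigma_-))` on
attention-pooled features — the published table prints separation values
without a formula, so absolute values are not comparable across
implementations; only orderings are, and our ablation asserts orderings
only. One-way ANOVA across models uses the classic equal-variance F test;
all-identical inputs return NaN with a warning rather than a fabricated
statistic.

The ablation trains four variants under identical budgets and seeds —
CNN+LSTM, + multi-head attention, + transformer encoder, + margin
attention. Its protocol is subject-independent: per seed, one whole
subject (cycled across seeds) is held out for testing and the variants
share the identical training/validation split of the remaining subjects.
Two reasons for this choice. First, it is the evaluation regime used for
every other result in this problem setting, so the ablation measures the
same quantity. Second, a pooled within-distribution 70/15/15 split (still
available via `protocol = "pooled"`) saturates on this generator — every
CNN-family variant reaches F1 ≈ 0.98 and the between-variant ordering is
then dominated by seed noise, which makes the pooled ablation
uninformative about the attention mechanism. One held-out subject per
seed also keeps the study at 40 trainings where a full
leave-one-subject-out sweep per variant would need 320. Problem sizes
used by the packaged checks: 8 subjects x 200 trials, `erd_factor` 0.5,
10 seeds, 6 epochs per run at batch 128 — sizes chosen as the package's
own reduced-scale study conditions.

## 7. Numerical engine

A tape-based reverse-mode autodiff over base-R arrays: coarse ops
(BLAS matmuls, im2col convolution, a fused LSTM with hand-derived
backpropagation-through-time, batched attention) so the R-level overhead
per node is negligible. Every operation's vector-Jacobian product, the
fused LSTM, and the whole assembled model are checked against central
finite differences. Batch normalization always uses batch statistics (no
running averages); evaluation batches are large enough that this is
well-conditioned, and it keeps train/eval behavior identical — a
documented simplification. All randomness (initialization, shuffling,
splits, generator) flows from explicit integer seeds; seeded runs are
bit-reproducible.

## 8. Known limitations

* The margin layer's scores are linear per key; with frozen features it
  cannot up-weight class-informative keys for *both* classes when their
  signals point in opposite feature directions (see section 2 above). Joint training
  with the encoder is the intended regime.
* The transformer variant is a small single-block encoder by default and
  underperforms the CNN+LSTM backbone at the package's training budgets,
  consistent with transformers' appetite for data.
* Binary labels only; multi-class margin formulations are out of scope.
* EDF export writes plain EDF (int16, 1-s records) with events in a
  sidecar TSV rather than EDF+ annotations.
* Synthetic-data results bound what the tests can claim about real EEG
  (see section 3 above).
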