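---
title: "Pre-ictal EEG classification with a multi-frame network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-ictal EEG classification with a multi-frame network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preictal)
```

## The problem

Seizure prediction from EEG is framed here as a binary classification of
one-second multichannel segments: **pre-ictal** (the 30 minutes before a
seizure onset, the positive class) against **inter-ictal** (baseline
activity between seizures). Ictal spans and a post-ictal buffer are
excluded from both classes. A subject is eligible when it has at least
three seizures, so that leave-one-seizure-out evaluation is meaningful;
seizures closer than 30 minutes are merged and treated as one event.

## The dual representation

Every segment — an `N x M` matrix of `N` channels by `M = fs` samples — is
represented two ways, one per network branch.

**Instance view, `(2, N, N)` tensor.** Plane 1 is a per-segment PCA score
matrix: the channels are the observations, the `M` time samples the
features; features are mean-centred across channels and the `N`
observations are projected onto the first `N` principal axes. Because
centring `N` observations leaves rank at most `N - 1`, the last component
is always zero-filled; each component's sign is fixed so its
largest-magnitude loading is positive, making the output deterministic
across linear-algebra backends. Plane 2 is the `N x N` matrix of pairwise
channel Pearson correlations, symmetric with unit diagonal; any pair
involving a flat-lined (zero-variance) channel is assigned correlation 0
so tensors stay finite. PCA is fitted per segment, not per recording: the
score matrix must have shape `(N, N)` for a single segment, which forces
the per-segment reading.

**Sequence view, raw `N x M` matrix.** The segment's columns are consumed
in time order as a length-`M` sequence of `N`-vectors.

## The four architectures

* **CNN (instance-based):** three blocks of
  [conv → batch norm → ReLU] on the 2-plane `N x N` image, with 2x2 max
  pooling after blocks 1 and 2 only; the final map is flattened.
* **LSTM (sequence-based):** a single LSTM layer whose final hidden state
  is the feature; the reference width is 256 units.
* **CNN-LSTM (sequential baseline):** the same conv stack, whose
  pre-flatten map is unrolled along one spatial axis into a sequence of
  (height x filters)-dimensional vectors fed to the LSTM. This wiring is
  one reading of an under-specified design; it is chosen because it
  preserves a genuine sequence for the recurrent stage, and it is
  configurable in `model_spec()`.
* **Multi-frame:** CNN and LSTM branches run in parallel on the two views
  of the same segment; their features are concatenated.

All four end in the same fully connected head — 128 and 64 units with ReLU
and dropout 0.5, then a 2-way softmax. Dropout acts only during training,
so inference is deterministic. Convolution hyper-parameters
(filters 32/64/128, 3x3 kernels, stride 1, same padding) follow the
conventional LeNet/AlexNet-style schedule; they are not uniquely pinned
down by the reference description, so `model_spec()` exposes all of them.

The networks, backpropagation and the Adam optimizer are implemented in
vectorised base R (BLAS matrix products); analytic gradients for every
layer and every architecture are verified against central finite
differences in the test suite.

## Training

Mean binary cross-entropy (predictions clipped at `1e-7`) is minimised
with Adam. Reference settings are batch 512 and learning rate 3e-4; the
batch is automatically capped at the training-set size. Termination is by
early stopping — patience on the validation loss with best-checkpoint
restore — because the reference recipe does not state an epoch budget.
`train_cfg()` also exposes an optional decoupled weight decay (default 0).
At desk scale it matters: small noisy tasks are memorised long before a
generalising feature is found, the validation *loss* then explodes from
overconfident errors even while validation accuracy improves, and the
best-loss checkpoint degenerates to an early chance-level epoch. A decay
of ~0.3 at learning rate 1e-3 keeps the loss aligned with accuracy.

Whether the raw sequence fed to the LSTM should be standardized is left
open by the reference description; `standardize_recording()` implements
per-recording channel z-scoring and is **off by default**. The simulation
studies below enable it: the generator produces microvolt-scale signals
whose magnitude saturates LSTM gate nonlinearities at standard weight
initialisation, while the correlation plane is provably invariant to
per-channel affine rescaling, so standardization helps the sequence branch
and cannot harm the instance branch.

## Evaluation

Leave-one-seizure-out: with `K` pre-ictal blocks, fold `k` tests all
segments of pre-ictal block `k` plus one inter-ictal block, and the rest
splits 80/20 into train/validation, stratified by class. How inter-ictal
data maps to folds is unspecified in the reference protocol; here the
balanced inter-ictal segments are partitioned in time order into `K`
equal contiguous runs, paired with pre-ictal blocks chronologically.
Metrics per fold are accuracy, sensitivity (= recall), specificity,
precision, F1 and trapezoidal ROC AUC, with pre-ictal as positive;
threshold 0.5, ties counted positive; degenerate denominators yield 0
plus a flag. Fold metrics are averaged arithmetically (per-fold AUC then
mean, not pooled). Class balancing — subsampling inter-ictal segments to
the pre-ictal count — happens per subject before fold construction.

## The synthetic generator

`generate_subject()` lays out `n_seizures` repetitions of
inter-ictal block → pre-ictal block → 20 s ictal event (a high-amplitude
3 Hz oscillation generated only so labelling code has something to
exclude). Each channel is a sum of

* broadband AR(1) noise (coefficient 0.6, stationary sd 5), and
* three band-limited Gaussian noise packets — theta 4–8 Hz, alpha
  8–13 Hz, beta 13–30 Hz — built by restricting white noise to the band
  in the frequency domain.

Independent per-channel sources are mixed through the Cholesky factor of a
compound-symmetric channel correlation matrix, which sets the
cross-channel correlation exactly without altering per-channel spectra.
The pre-ictal regime differs from inter-ictal along exactly the two axes
the two branches exploit, both scaled by the effect size `delta`:

* `corr_shift`: the off-diagonal correlation rises from `base_corr`
  (default 0.2) by `delta * corr_shift` (default 0.3);
* `spectral_shift`: a fraction `delta * spectral_shift` of alpha-band
  power moves half to theta and half to beta, total power preserved.

The inter-ictal band-power profile is alpha-dominant (theta 6, alpha 40,
beta 6, in signal-variance units against noise variance 25), mirroring the
alpha dominance of resting EEG; the pre-ictal shift is then an alpha
suppression, a temporally accessible cue (it changes the short-lag
autocorrelation) that a recurrent model can learn. Band-limited *noise*
rather than fixed sinusoids matters for evaluation: every segment of every
block then carries energy across the whole band, so the spectral cue
generalises across blocks instead of reducing to block-specific
frequencies that a leave-one-block-out test would never have seen.
At `delta = 0` the two regimes are identically distributed by
construction. Amplitudes are arbitrary microvolt-like units; the
correlation plane is scale-invariant and nothing else in the pipeline is
scale-sensitive by design.

What the generator does **not** emulate: 1/f background structure,
artifacts (eye blinks, EMG, electrode pops), non-stationary drift between
blocks, and realistic seizure morphology. Passing the simulation studies
therefore shows that the pipeline recovers the two feature modes it
targets under controlled conditions — not that it attains any particular
performance on clinical recordings.

## Simulation study design and problem sizes

The packaged studies (in the acceptance tests and
`scripts/acceptance.R`) use problem sizes chosen to keep a full run on a
single desktop core in the tens of minutes while leaving every
statistical conclusion unambiguous:

* **Null and dual-signal subjects:** 8 channels at 64 Hz, 3 seizures,
  2 min inter-ictal + 1 min pre-ictal per block (360 balanced segments).
* **Signal recovery:** the full-size recording format, 16 channels at
  256 Hz, 3 seizures, 3 + 2 min blocks (720 segments).
* **Correlation-only subject:** as the dual subject with
  `spectral_shift = 0`.
* **Spectral-only subject:** `corr_shift = 0`, `spectral_shift = 1`
  (the alpha band fully relocated), and more data — 4 seizures,
  4 + 3 min blocks (1,440 segments) — because the sequence-mode cue has
  a much lower per-segment signal-to-noise ratio than the correlation
  cue and the LSTM needs the extra segments to generalise rather than
  memorise.
* **Networks for these studies:** conv filters 8/16/32 and 32 LSTM
  units — the same topology as the reference architecture at reduced
  width; `model_spec()` defaults remain at the full 32/64/128 and 256.
* **Recipe:** Adam, learning rate 1e-3, weight decay 0.3, batch 32–64,
  up to 60–100 epochs.

Generator calibration was validated against independent oracles before
the studies were frozen: at `delta = 1` a logistic regression on FFT band
powers reaches AUC ≈ 0.95 and the mean off-diagonal segment correlation
separates the classes at AUC ≈ 1.0, while the recovered correlation shift
is 0.30 ± 0.01; at `delta = 0` both oracles sit at chance.

## Numerical choices and degenerate inputs

* Pearson pairs with a zero-variance channel → 0 (diagonal stays 1).
* PCA components beyond the centred rank → zero columns; component signs
  fixed by the largest-magnitude loading.
* Probabilities clipped at `1e-7` in the loss; softmax uses the max-shift
  trick.
* Max pooling breaks ties by first occurrence; odd spatial extents floor
  (15 → 7 → 3).
* Batch-norm: statistics over batch x spatial positions per feature map,
  momentum 0.9, eps 1e-5; inference uses running averages.
* LSTM forget-gate bias initialised to 1; all weights Glorot-uniform from
  a seeded generator, so initialisation is bit-reproducible.
* Interval labelling excludes a configurable post-ictal buffer
  (default 30 min, symmetric with the pre-ictal horizon) because
  post-ictal activity belongs to neither class; synthetic runs shorten it
  to 15 s since the generator returns to baseline immediately after the
  ictal event.
* A pre-ictal window swallowed entirely by a previous exclusion zone
  yields no block, with a warning; recordings without seizures label
  everything inter-ictal, with a warning.

## Known limitations

* The EDF reader/writer targets continuous 16-bit recordings with one
  sampling rate across channels — sufficient for round-tripping and for
  CHB-MIT-style files, not a general EDF+ implementation.
* Training is single-threaded R; the reference-width multi-frame network
  (256 LSTM units at 256 Hz) trains slowly and is intended for real-data
  scale, not for the bundled simulations.
* Event-level seizure-prediction metrics (false prediction rate per hour,
  prediction horizon analysis) are out of scope; evaluation is per
  segment.
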