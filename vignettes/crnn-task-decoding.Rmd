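---
title: "Decoding task states from 4D fMRI with a convolutional-recurrent network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding task states from 4D fMRI with a convolutional-recurrent network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmricrnn)
```

## The problem

Task-evoked fMRI measures the blood-oxygen-level-dependent (BOLD) signal of
the whole brain every TR = 0.72 s while a subject performs a task paradigm.
`fmricrnn` classifies short 4D clips of such data into one of seven task
states (Emotion, Gambling, Language, Motor, Relational, Social, Working
Memory), using one representative condition per paradigm — Fear, Loss,
Story, LeftHand, Relation, Mental and 2bk_places, with block durations of
18, 28, 24, 12, 16, 23 and 27.5 s respectively. The decoder treats fMRI as
what it is: a *spatiotemporal* signal. A time-distributed 3D convolution
stack extracts spatial activation patterns per frame, a bidirectional LSTM
models their temporal evolution, attention pooling weights the informative
time points, and a small dense softmax head produces the 7-class
prediction.

## Preprocessing model

Raw runs are 91 × 109 × 91 voxel volumes over time, assumed already aligned
to MNI152 space (no motion correction or smoothing is performed here).
Preprocessing proceeds in six steps:

1. **Crop.** Peripheral black borders are removed, 91 × 109 × 91 →
   78 × 93 × 76 (551,304 voxels). Only the target size is prescribed by the
   design; we center the crop (leading margins 6, 8, 7), the neutral
   reading of "remove borders", and make the margins configurable.
2. **Block extraction.** A condition block of duration $TD$ spans
   $TF = \mathrm{round}\!\left((TD + 8)/0.72\right)$
   frames — the block itself plus an 8 s post-stimulus window that captures
   the delayed hemodynamic response. Rounding is to the nearest integer
   (half away from zero): it is the unique simple rule consistent with all
   seven published frame counts (27.78 → 28 rules out flooring, 36.11 → 36
   rules out ceiling), giving 36, 50, 44, 28, 33, 43, 49 frames for the
   seven conditions. Onsets are converted to frames by
   $\mathrm{round}(\text{onset}/TR)$.
3. **Window augmentation.** Because block lengths differ across tasks, 21
   consecutive frames are drawn from each block, with the start index
   uniform over the valid range (with replacement).
4. **Balancing.** Each subject contributes exactly 12 windows per task,
   distributed as evenly as possible across that task's blocks (remainders
   to the earliest blocks): 12/4 = 3 draws per Story block, all 12 from the
   single Working-Memory block. Per-run block counts are 2, 2, 4, 2, 3, 2,
   1, so one subject yields 84 samples.
5. **Inter-frame differencing.** Consecutive frames are subtracted and the
   absolute value taken, turning 21 frames into 20 and highlighting voxels
   whose intensity is *changing* — the signature of an evolving
   hemodynamic response — while cancelling static anatomy.
6. **Max normalization.** Each sample is divided by its single scalar
   maximum over all 20 frames, so values land in [0, 1] with a global
   maximum of exactly 1. We read the normalization denominator as the
   scalar maximum rather than an elementwise division by the brightest
   frame, because the latter is undefined wherever that frame is zero.
   All-zero samples (possible only for degenerate constant input) pass
   through unchanged with a warning. A consequence worth testing — and
   tested — is that preprocessing is exactly invariant to rescaling the raw
   run by any positive constant.

The model-ready sample is a rank-5 array `[20, 78, 93, 76, 1]`
(time, x, y, z, channel). Splits are **by subject** — 80 % train, 10 %
validation, 10 % test, and a 10-fold variant in which every subject appears
in exactly one test partition — so no person's data straddles partitions.

## Architecture

The convolution stack (all valid padding, stride replacing pooling):

| stage | kernel | channels | stride | output |
|-------|--------|----------|--------|--------|
| input | — | 1 | — | [20, 78, 93, 76, 1] |
| conv1 | 7×7×7 | 32 | 2 | [20, 36, 44, 35, 32] |
| conv2 | 3×3×3 | 64 | 2 | [20, 17, 21, 17, 64] |
| conv3 | 3×3×3 | 64 | 2 | [20, 8, 10, 8, 64] |
| conv4 | 8×10×8 | 64 | 1 | [20, 1, 1, 1, 64] |

Each block is convolution → batch normalization → ReLU, applied
*time-distributed*: the identical kernels act independently on every frame,
so the time axis is preserved — the package verifies this against a
per-frame brute-force convolution oracle. The fourth block is a *full
convolution*: its kernel equals the incoming 8 × 10 × 8 feature map, so the
spatial dimensions collapse to 1 × 1 × 1 and the output squeezes to a
[20, 64] feature sequence.

The recurrent stage is a single bidirectional LSTM, 64 units per
direction, standard gate equations, zero initial states, outputs
concatenated to [20, 128], with dropout 0.2 on its outputs during training.
The architecture's own parameter budget settles a wording ambiguity ("two
hidden LSTM layers" vs. "two layers with opposite directions"): one
bidirectional layer contributes 2 × 33,024 = 66,048 parameters, exactly
matching the published tally, whereas a stacked pair would not.

**Attention.** The published weighting formula exponentiates a whole hidden
vector, which is dimensionally ambiguous. The parameter budget again
adjudicates: additive attention with a 64-dimensional tanh projection
($W_a \in \mathbb{R}^{128\times64}$, $b_a \in \mathbb{R}^{64}$) and a
learned context vector $u_a \in \mathbb{R}^{64}$ contributes
128·64 + 64 + 64 = 8,320 parameters — precisely the residual left by the
convolutional, recurrent and dense tallies. Scores
$s_j = u_a^\top \tanh(W_a h_j + b_a)$ are softmax-normalized over the 20
time steps and the context is the weighted sum $c = \sum_j w_j h_j$. The
literal parameter-free reading (elementwise softmax of the hidden values
over time) is also implemented behind `attention_type = "literal"`; additive
is the default.

The classifier is dense 128 → 64 with ReLU, then dense 64 → 7 with
softmax; training minimizes cross-entropy. The analytic inspectors
reproduce the full budget without allocating a single tensor:

```{r params}
pc <- count_parameters(crnn_config())
pc
```

Total 2,882,503; trainable 2,882,055; the 448 non-trainable entries are
exactly the batch-norm moving means and variances, 2 × (32+64+64+64).

## Training protocol

Adam with initial learning rate 0.001 ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-7}$, the framework defaults of the era), batch size 8.
After every epoch the validation accuracy is measured; the best-scoring
parameters are retained (ties broken by lower validation loss) and training
stops after a patience of 10 non-improving epochs (default) or at the
epoch cap. The stated stopping rule is qualitative — "loss flattens or
validation accuracy stops rising" — and patience is its standard
quantitative form. Every source of randomness (initialization, shuffling,
dropout, window draws) flows from explicit seeds, and the training loop
refuses subject leakage between partitions outright.

Since no deep-learning framework is part of this package's dependency
footprint, the forward *and* backward passes are implemented in the
package itself — R matrix algebra plus two Rcpp kernels for the 3D
convolution — and every layer's analytic gradient is verified against
central finite differences in the test suite (worst relative error on the
order of 10⁻⁶).

Numerical choices: batch normalization uses $\epsilon = 10^{-3}$ and
normalizes per channel jointly over batch, time and space, matching the
time-distributed wrapper semantics; weights are Glorot-uniform with
forget-gate biases initialized to 1; batch-norm order is normalize → scale
→ ReLU, following the stated equations. The moving-statistics momentum is
0.99 at full scale; the reduced desk-scale configuration uses 0.9 because
it takes roughly two orders of magnitude fewer optimizer steps per epoch,
and inference statistics must converge within the few epochs such a model
needs. Cross-entropy is computed from logits via log-sum-exp, so it is
defined for any input.

## The synthetic generator

Real HCP data cannot ship with a package, so `sim_config()` /
`generate_dataset()` emulate the data model end-to-end: per subject and
task, a 4D run at baseline 100 containing that task's blocks (published
durations and block counts, evenly spaced onsets with a 12 s lead-in and
14 s inter-block rest) as a boxcar convolved with a canonical double-gamma
HRF (peak ≈ 5 s, undershoot ≈ 15 s, normalized to peak 1), confined to a
task-specific spherical ROI on a fixed 7-point lattice inside the cropped
box, plus i.i.d. Gaussian noise everywhere and a slow sinusoidal drift.
Defaults — 3 % activation amplitude, noise SD 1, baseline 100 — are typical
BOLD-like magnitudes. Runs can be written as NIfTI + event files and fed
through the identical preprocessing path as real data.

What the generator does *not* emulate: anatomy, physiological and motion
noise, spatially correlated noise, inter-subject variability of ROI
placement, or overlapping functional networks. Passing the training test
therefore shows that the implementation can learn separable spatiotemporal
structure end-to-end — a correctness property of the pipeline and
optimizer — not that the architecture would reach any particular accuracy
on real HCP data.

## Desk-scale problem sizes

The package's own experiments run on reduced volumes of 24 × 28 × 24
voxels (cropped proportionally to 20 × 24 × 20) with a matching reduced
stack (`reduced_crnn_config()`: 5³/8/s2 → 3³/16/s2 → full 3×4×3/16, 16
LSTM units per direction, 16-dim attention, 16 dense units, 19,207
trainable parameters). The training check uses 10 subjects (8/1/1 split,
840 samples), a clearly separable generator setting (amplitude 0.5, noise
SD 0.2), an epoch cap of 12 with patience 4, and a label-shuffled ablation
trained identically whose held-out accuracy must stay within the binomial
confidence band of chance (1/7) — the standard guard against hidden
leakage. The full-size architecture is exercised through the analytic
inspectors, which is how the published parameter and shape figures are
reproduced exactly without full-scale training.

## Known limitations

- The full 91 × 109 × 91 model trains only in principle here: a forward
  pass allocates multi-hundred-MB intermediates and CPU-only training at
  that scale is not practical; the published HCP accuracy figures are
  out of scope for this package's experiments.
- The sample container is an RDS file (with a JSON manifest) rather than
  HDF5.
- Whether the published ± figures denote standard deviation or standard
  error across folds is not stated in the source; `cross_validate()`
  reports the standard deviation.
- The 8 s post-stimulus window is extracted even when it overruns into a
  following rest period or block; excluding such overlaps is left to the
  caller's event timing.
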