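---
title: "Scalp-to-intracranial EEG translation: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scalp-to-intracranial EEG translation: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ieegmap)
```

## The problem and the model

Interictal epileptiform discharges (IEDs) — spikes or sharp waves, usually
followed by a slow wave — arise from deep sources that foramen-ovale (FO)
intracranial electrodes record cleanly but that reach the scalp attenuated,
spatially mixed, and often buried in background rhythms and artifacts.
`ieegmap` learns a mapping from a 64-sample, 12-channel scalp segment
**X** to an estimate **Ỹ** of the concurrent 12-contact intracranial
segment **Y**, then classifies **Ỹ** as IED or non-IED.

The translator is a conditional GAN. The generator is a 1-D U-net over the
time axis: a contracting path of kernel-5 time convolutions, each followed
by per-segment time-axis normalization and stride-2 average pooling, with
feature channels doubling at every level (16, 32, 64 from a base of 16,
with a 128-wide bottleneck at time length 8); an expansive path of
bilinear 2× upsampling, a 1×1 feature-halving convolution, concatenation
with the matching contracting feature map, two kernel-5 convolutions and a
time-axis normalization per level; then a final 1×1 convolution and a
time-distributed dense map to the 12 output channels. The discriminator
consumes the channel-wise concatenation (X, Y) or (X, Ỹ) — 64×24 — through
three kernel-5 convolution blocks (ReLU, dropout 0.25, stride-2 max
pooling; widths 32/64/128) and a dense sigmoid unit.

Training alternates one discriminator step ascending

    L_GAN(G, D) = E[log D(X, Y)] + E[log(1 − D(X, G(X)))]

with one generator step descending the adversarial term plus
`lambda_l2 * E || Y − G(X) ||_2` — the per-segment Frobenius *norm*
(the printed form; a squared variant is available via
`translator_config(l2_squared = TRUE)`).

The detector is an EEGNet-style compact CNN — temporal convolution
(kernel 32, shared across channels), depthwise spatial convolution over
the 12 channels, separable temporal convolution, ELU activations,
dropout — with two deliberate modifications: every batch-normalization
stage is removed and every pooling stage is max pooling. F1 = 8, D = 2,
F2 = 16 follow the standard EEGNet defaults; the temporal kernel of 32 is
half the segment length, mirroring EEGNet's half-sampling-rate rule at
segment scale.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `lambda_l2` | 100 | weight (unitless) of the L2 norm in the generator loss; standard for L-regularized translation GANs. With standardized segments the L2 term dominates early training and drives supervised convergence; the adversarial term sharpens waveform detail. |
| `base_feature_channels`, `n_levels` | 16, 3 | U-net width/depth; chosen so the whole GAN (204,157 parameters) sits under the 0.25 × 10⁶ complexity budget |
| `kernel_time` | 5 | time-axis kernel (samples) in both GAN networks |
| `dropout_rate` | 0.25 | discriminator / detector dropout |
| `learning_rate` | 1e-3 | Adam step size for both networks (see below) |
| `adversarial_mode` | `"non_saturating"` | generator maximizes log D on fakes; shares fixed points with the literal minimax objective (available as `"minimax"`) but does not saturate when the discriminator wins early |
| detection threshold | 0.5 | canonical under the enforced 1:1 class balance |

All training is a pure function of (data, config, seed): initialization,
batch shuffling, and dropout masks derive from the config seed, and
repeated runs give bit-identical loss histories.

## Design choices made where the design was open

- **Adversarial mode.** The literal minimax generator gradient vanishes
  when the discriminator dominates, which at these batch counts happens
  within an epoch; the non-saturating heuristic is therefore the default
  while the minimax objective remains selectable. Both share the same
  optimum.
- **"Normalization across the time domain"** is implemented as
  per-segment, per-feature-channel standardization over the 64 time steps
  with a learnable affine — batch-independent, so inference does not
  depend on batch composition.
- **Learning rate.** At this parameter budget and the short schedules used
  throughout (≤ 30 epochs, a few hundred updates), an Adam rate of 2e-4 —
  customary for large image-translation GANs — leaves the generator near
  the trivial predict-the-mean optimum (standardized L2 ≈ 27 against
  √768 ≈ 27.7 for an all-zero prediction). The default is therefore 1e-3,
  at which the generator converges stably (L2 ≈ 23 on the reference
  cohort) while remaining config-exposed.
- **Data scaling.** Segments are standardized per channel with
  training-set statistics before entering either network; the inverse
  transform is applied to Ỹ so reported L2 distances and translated
  waveforms are in µV.
- **One convolution per contracting level, two per expansive level** — a
  literal reading of the architecture that also keeps the parameter count
  within budget; the discriminator's three blocks likewise.
- **Windowing.** "32 samples before and after the peak" is read as the
  half-open window [p − 32, p + 32), 0-based — 64 samples total, matching
  X ∈ ℝ⁶⁴ˣ¹²; the inclusive 65-sample reading is rejected.
- **Non-IED sampling.** The distance non-IED windows must keep from spikes
  is unspecified in the source protocol; this package enforces a 64-sample
  guard interval on each side of every annotated peak (so no non-IED
  window overlaps any guard zone) and draws candidates from a
  non-overlapping 64-sample grid, balancing classes by seeded subsampling
  of the majority class.
- **Filters.** The filter family is unspecified; a 4th-order Butterworth
  band-pass (1–70 Hz) and a Q = 30 biquad notch (50 Hz), both applied
  forward–backward (zero-phase), are standard clinical practice, and
  zero-phase filtering preserves the spike-peak latency that peak-centred
  segmentation depends on. The intracranial signal is filtered identically
  but not re-referenced; the common average reference applies to the scalp
  montage only, before the 12-channel selection.
- **LOSO ensemble.** "High accuracy" training-subject selection is
  formalized as intra-subject accuracy ≥ 0.70 (configurable). One detector
  is trained per translator G_n on that translator's outputs pooled over
  all selected training subjects — the parallel-branch reading of the
  ensemble diagram; per-branch probabilities are averaged (average voting)
  and thresholded at 0.5.

## The synthetic cohort: what it emulates and what it does not

The simulator reproduces the *structure* of concurrent scalp/FO epilepsy
monitoring: 200 Hz sampling; 20 scalp channels (10–20-style labels) and
12 FO contacts in two 6-contact bundles; per-subject IED counts in the
reported 50–953 range (or fixed per configuration); spike-plus-slow-wave
morphology (70 ms sharp component, 350 ms slow wave, per-event amplitude
and shape jitter); a subject-fixed focal unit-norm source pattern over the
contacts; a scalp projection obtained through a distance-based mixing
matrix scaled so the strongest scalp channel's peak equals
`seeg_attenuation` × the source amplitude; 1/f^α background noise (α = 1)
on both modalities, much weaker intracranially (`ieeg_snr_db` = 15); a
10 Hz posterior rhythm and eye-blink-like frontal artifacts on the scalp
only; and a controlled scalp-visibility fraction — exactly
`visibility_fraction` of events keep their full scalp gain, the rest are
suppressed so their noise-free scalp projection falls to 35% of the scalp
background RMS. Peaks are annotated from the intracranial ground truth
regardless of scalp visibility, with ≥ 1 s refractory gaps and a
100-sample edge margin so segmentation never truncates.

It does **not** attempt biophysically accurate head modelling (no BEM/FEM
lead fields), non-stationary background, electrode drift, poly-spike
morphology families, or realistic artifact diversity. Consequently,
passing synthetic-recovery tests demonstrates that the implementation
learns the intended mapping under the stated forward model — not that the
clinical accuracies reported for any private dataset would be reproduced.
The background-noise model is a stand-in, not a claim about clinical data.

## Numerical choices

- Probabilities are clamped at 1e-7 inside logarithms; per-segment norms
  at 1e-8 in the L2 gradient.
- Per-segment time normalization uses ε = 1e-5 inside the square root.
- Bilinear 2× upsampling interpolates linearly between consecutive time
  steps with edge replication.
- Max-pool ties resolve to the earliest element; average pooling is exact.
- Adam uses β₁ = 0.5 (GAN) / 0.9 (detector), β₂ = 0.999, ε = 1e-8.
- All gradients are hand-derived and verified against central finite
  differences in the test suite (relative tolerance 1e-4 with an absolute
  floor for the exactly-zero gradients of conv biases that feed a
  normalization layer).

## Problem sizes used by the shipped tests and acceptance script

Unit and protocol tests run on miniature cohorts (tens of events, 100 s
recordings, 2-epoch trainings) that exercise every contract cheaply. The
synthetic-recovery evaluation uses the reference cohort of 6 subjects ×
200 IEDs at 15% visibility with 25 translator epochs and 20 detector
epochs — enough for the translator to converge under the default
configuration while keeping a full run to minutes on a single CPU. The
intra-subject protocol there yields mean held-out accuracy ≈ 0.87 from
translated segments versus ≈ 0.75 from raw scalp segments, and roughly
triples the held-out correlation with the true intracranial waveform —
the package's own quantitative account of why the translation step is
worth its cost.

## Known limitations

- The exact layer counts of the original architecture diagrams are not
  recoverable from text; only the printed 0.25 × 10⁶ total constrains the
  implementation, which reaches 204,157 parameters.
- Training runs single-threaded; reproducibility is exact on a given
  BLAS, and numerically equivalent elsewhere.
- The EDF writer/reader implements the classic 16-bit format only (no
  EDF+ annotations); IED peaks travel in a CSV sidecar.
- Real-data ingestion assumes 200 Hz input; no resampling, montage
  interpolation, or artifact-rejection preprocessing is provided.
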