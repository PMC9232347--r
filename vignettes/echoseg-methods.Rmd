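---
title: "Methods: octave-convolution attention U-Net++ for echocardiography segmentation"
author: "echoseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: octave-convolution attention U-Net++ for echocardiography segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Dynamic echocardiography produces grayscale video of the beating heart inside
a fan-shaped field of view (the *sector*). Compared with CT or MR, the images
are noisy — coherent ultrasound produces multiplicative *speckle* — and the
chamber of interest occupies only part of the frame. `echoseg` implements a
complete, CPU-reproducible pipeline for segmenting the cardiac chamber in
such sequences:

1. **Sequence-level preprocessing** finds the sector once per video.
2. A **segmentation network** labels each pixel of each frame.
3. An **evaluation suite** scores predictions against expert-style masks.
4. A **synthetic phantom generator** provides seeded data so that every
   result in this package can be recomputed from scratch on one CPU.

# Sector detection

A single frame only insonifies part of the sector, but over a cardiac cycle
every sector pixel lights up at some point. The *maximum-intensity
projection* `M(x, y) = max_k I_k(x, y)` therefore reveals the full fan while
the outside of the fan stays black. The projection is thresholded with
Otsu's method (256-bin histogram over [0, 1]; a fixed-fraction threshold is
available as a config option), refined by morphological closing then opening
with a disk of radius 5 px, and the largest 8-connected component is kept.

Two choices here are the package's own, since only the operations — not
their parameters — are standard:

* **Hole filling.** The blood pool is dark in *every* frame, so the chamber
  survives as a large hole in the thresholded projection; a radius-5 closing
  cannot bridge a hole tens of pixels wide. Because the sector is by
  definition a solid region, `refine_sector()` fills interior holes of the
  surviving component (`fill_holes = TRUE`, configurable). This was decided
  from the geometry of the projection image, and without it the recovered
  sector would exclude the chamber.
* **Normalization.** Frames are min-max rescaled jointly over the sequence
  before projection, preserving inter-frame intensity relations.

# Octave convolutions

An octave feature stores a fraction `alpha` of its channels as a
half-resolution low-frequency stream `X^L` and the rest at full resolution
(`X^H`). One octave convolution exchanges information along four paths:

$$Y^H = \mathrm{Conv}(X^H, W^{H\to H}) + \mathrm{Up}(\mathrm{Conv}(X^L, W^{L\to H}), 2)$$
$$Y^L = \mathrm{Conv}(\mathrm{AvgPool}(X^H, 2), W^{H\to L}) + \mathrm{Conv}(X^L, W^{L\to L})$$

with stride-1 same-padded convolutions throughout. Channel splits follow
`c_L = round(alpha * c)`; at `alpha = 0` the operator is exactly an ordinary
convolution (this degeneracy is tested against a brute-force convolution
oracle). Defaults, each configurable:

| parameter | default | rationale |
|---|---|---|
| `alpha` | 0.5 | an even split; the same value feeds every interior layer |
| kernel size | 3 | standard for encoder-decoder CNNs |
| low-to-high upsampling inside the operator | nearest | the convention of the octave-convolution literature |
| decoder upsampling | bilinear (half-pixel centers, no corner alignment) | smooth feature restoration |

The often-quoted claim that octave convolution costs a quarter of a dense
convolution does not follow from the operation count: at `alpha = 0.5` the
multiply-accumulate ratio is `(1-a)^2 + a(1-a)/2 + a^2/4 = 7/16`, and 1/4 is
approached only as `alpha -> 1`. `oct_conv_cost_ratio()` reports the computed
ratio instead of asserting the quoted figure.

# CBAM attention

At every decoder fusion the concatenated features pass through a
convolutional block attention module: a channel gate
`M_c = sigmoid(MLP(AvgPool F) + MLP(MaxPool F))` with a shared two-layer MLP
(hidden width `max(1, floor(C/r))`, `r = 16`, ReLU in between), followed by
a spatial gate built from channel-wise mean and max maps passed through a
same-padded 7x7 convolution and a sigmoid. Both gates lie strictly in
(0, 1), so the gated feature never exceeds the input in magnitude. The 7x7
convolution zero-pads; on a spatially constant input the gate is constant
except within 3 px of the border, where the padding is visible. By default
the gate is applied to the high-frequency stream only (`cbam_streams =
"high"`); gating the low stream as well is available but was not observed to
be necessary on the phantom task.

# Network topology

The model is a nested U-Net++ grid of nodes `X^{i,j}` (`i + j < depth`,
`depth(depth+1)/2` nodes), every feature being a high/low octave pair:

* The stem is an *initial* octave convolution (all-high input, establishes
  the split); encoder levels are connected by 2x2 average pooling per
  stream.
* Each decoder node bilinearly upsamples its lower-level predecessor,
  concatenates all same-level, same-scale predecessors (the dense U-Net++
  skips), applies CBAM to the fusion, and runs a block of `block_convs = 2`
  octave convolutions.
* The head is a *final* octave convolution merging both streams into one
  channel, followed by a sigmoid.

Each convolution is followed by per-channel spatial normalization with
learnable scale and shift and running evaluation statistics — the form
BatchNorm takes at batch size one, which is how this package trains on CPU —
then ReLU. Deep supervision of intermediate heads is off by default. Inputs
whose sides are not divisible by `2^depth` are letterbox zero-padded and the
output cropped back; clinical 600x800 frames, for instance, run as 608x800
at depth 5.

# Losses

The soft Tversky index of a probability map `Y` against a crisp mask `X` is

$$TI = \frac{|X \cap Y| + s}{|X \cap Y| + \alpha\,|X - Y| + \beta\,|Y - X| + s}$$

with soft set operations (`|X∩Y| = Σ xy`, `|X−Y| = Σ x(1−y)`,
`|Y−X| = Σ (1−x)y`) and smoothing `s = 1` so empty masks give `TI = 1`
rather than 0/0. `alpha = beta = 0.5` reduces `TI` to the Dice coefficient —
the identity that fixes the denominator's standard form. The focal Tversky
loss is `FTL = (1 − TI)^gamma` for the single foreground class, `gamma` in
[1, 3], default 2: larger exponents up-weight hard, low-overlap samples.
Defaults `alpha = 0.7, beta = 0.3` penalize missed foreground more than
false alarms, the usual imbalance handling. Dice loss and mean binary
cross-entropy (probabilities clipped at `1e-7`) are provided as baseline
objectives selectable by name in the training config.

# Metrics

With `A` the expert annotation and `B` the prediction, the suite reports
`AOM = |A∩B|/|A∪B|` (Jaccard), the miss fractions `AVM = |A−B|/|A|` and
`AUM = |B−A|/|B|`, the combined measure `CM = (AOM + (1−AVM) + (1−AUM))/3`,
plus `Sen = TP/(TP+FN)` and `Spe = TP/(TP+FP)`. Note that this `Spe` is the
*precision* form; it is kept because it satisfies the exact identities
`Sen = 1 − AVM`, `Spe = 1 − AUM`, and the conventional specificity
`TN/(TN+FP)` is reported alongside as `spe_conventional`. All metrics are
computed from integer pixel counts before any division. Conventions for
degenerate inputs: an empty annotation is an error (`AVM` undefined); an
empty prediction yields `AOM = 0, AVM = 1` and `AUM := 1` by convention
(maximal under-coverage penalty, with a warning) so `CM` stays defined.

ROC curves pool pixels within one image, sweeping the threshold over the
observed probability values; multi-image evaluation macro-averages
per-image metrics, matching per-case clinical reporting. The trapezoidal
area equals the Mann-Whitney pairwise statistic (tested against a
pair-counting oracle); a constant map yields the chance diagonal.

# The synthetic phantom

The generator emulates the data regime of a dynamic cardiac ultrasound
study — not its anatomy. Each sequence contains, inside a 70-degree sector:
a dark elliptical blood pool (`chamber_intensity = 0.12`), a bright
myocardial band around it (`wall_intensity = 0.85`, outer boundary fixed at
1.35x the base axes so the wall thickens in systole), and mid-level tissue
(`0.40`). The chamber semi-axes scale by `1 − a (1 − cos 2πt/T)/2` with
amplitude `a = 0.3` over a cycle of `T = 8` frames — periodic
diastole/systole-like area modulation with a max/min area ratio of
`1/(1−a)^2`. Speckle is multiplicative: two unit-variance Gaussian fields,
smoothed by a 1 px Gaussian point-spread (then re-standardized) and combined
as `(g1^2 + g2^2)/2`, give a Rayleigh-power-like field with unit mean that is
blended at weight 0.5. Per-sequence geometry jitter (center ±4%, axes ±10%,
random cycle phase) makes train and test sequences genuinely different;
splits are by sequence, never by frame, to avoid leakage.

What the phantom does *not* model: anatomically realistic four-chamber
views, probe motion, attenuation and shadowing, and Doppler. Passing tests
on the phantom therefore demonstrate that the pipeline's machinery is
correct and trainable under sector geometry, periodic deformation, and heavy
multiplicative noise — not clinical-grade performance on hospital data.

# Reference problem sizes and numerical choices

The package's reference experiment — used by its acceptance script and
end-to-end tests — runs 128x128 phantoms with a depth-3, base-8 network
(6 grid nodes), 10 sequences of 8 frames split 1:1 into 40 train and 40
test frames, focal Tversky loss, Adam at learning rate `1e-3`, one image
per update, 6 epochs. These sizes were chosen so that a full run completes
in minutes on a single CPU core while leaving a clear margin over the
package's quality bars (test mean AOM well above 0.85 in the reference
configuration; the same harness trains a cross-entropy baseline for
comparison). The clinical-scale 600x800 / depth-5 configuration is
supported but markedly slower; nothing in the code depends on the reduced
size.

Other numerical choices: He initialization from R's seeded RNG (bit-identical
builds from equal seeds); all randomness — initialization, shuffling,
speckle, jitter, splits — flows from explicit integer seeds, so repeated
runs are bit-identical on single-threaded BLAS; normalization uses
`eps = 1e-5` and momentum 0.1 for running statistics; probability clipping
at `1e-7` in cross-entropy; ties in channel-max pooling resolve to the first
index; training aborts with a diagnostic if the loss becomes non-finite.

# Known limitations

* Training is per-image (no mini-batching) and CPU-bound; the network code
  optimizes clarity and reproducibility over throughput.
* The checkpoint stores parameters and normalization statistics but not
  Adam moments; a resumed run continues epoch numbering with fresh
  optimizer state.
* The phantom's speckle is spatially stationary; real speckle statistics
  vary with depth and gain.
* Segmentation is per-frame after sequence-level sector detection; no
  temporal regularization across frames.
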