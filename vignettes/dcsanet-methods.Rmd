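---
title: "DCSAnet: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DCSAnet: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Mobile weeding equipment needs a segmentation model that separates crop from
weeds pixel by pixel while staying small enough for embedded hardware.
`dcsanet` implements such a network for soybean fields with four classes:
soil background (0), soybean (1), graminoid weed (2, grasses such as
*Digitaria* and *Setaria*) and broadleaf weed (3, e.g. *Chenopodium*,
*Amaranthus*). The two weed families respond to different herbicides, which is
why they are separated rather than pooled into one "weed" class.

The network is an encoder–decoder. The encoder is a 3×3 stride-2 stem followed
by three stages of **DCA blocks**, producing feature maps `feat1`, `feat2`,
`feat3` at 1/4, 1/8 and 1/32 of the input resolution. A DCA block is an
inverted-residual bottleneck in the MobileNetV3 family with three twists:

1. **Fourfold expansion, split in two.** A 1×1 convolution expands `C`
   channels to `4C`; the expanded map is split channelwise into two halves so
   each branch filters only half the features.
2. **Asymmetric depthwise convolutions at two scales.** Each half passes
   through a depthwise `N×1` followed by a depthwise `1×N` convolution. One
   branch uses the small kernel (3), the other the large one (the ablation
   knob `kernel_N`, default 7), giving a multiscale receptive field. The
   asymmetric pair costs a fraction `2/N` of a square `N×N` kernel; the
   depthwise + pointwise factorization costs `1/C2 + 1/N²` of a standard
   convolution (see `conv_flops()`).
3. **Channel shuffle.** Because each branch only ever sees a fixed half of the
   channels, the block output is permuted by the group-interleaving shuffle
   (reshape to `g×n`, transpose, flatten; `g = 2`, the number of branches), so
   the halves mix across consecutive blocks.

Mode A (stride 1) projects back to `C` channels and adds the block input as a
residual. Mode B (stride 2) applies the depthwise pair at stride 2, projects
to `C`, max-pools the block input to half size, and concatenates the two —
halving the resolution and doubling the channel count. Stages 1 and 2 are one
DCA-B plus one DCA-A each; stage 3 is `B, 3×A, B, 3×A`, with
squeeze-and-excitation channel attention in its last three A blocks.

The decoder upsamples `feat3` stepwise (bilinear, ×2 per step), fusing
`feat2` and `feat1` by channel concatenation + convolution on the way, and
refines at 1/2 and full resolution before a 1×1 classifier. In the guided
variants, `feat1` is first *guided* by a deep map: the guide (feat3 or feat2)
is refined by a 3×3 convolution at the decoder's intermediate 1/8 resolution,
upsampled to 1/4, channel-matched by a second 3×3 convolution, and multiplied
elementwise into `feat1`; the residual variants add the untouched `feat1`
back. The default variant is `feat3_guided_residual`.

Training minimises the mean pixelwise cross-entropy
`-(1/N) Σᵢ Σ_c y_ic log p_ic` (N = pixels in the batch) with Adam
(initial learning rate 0.001, batch size 4, 400 epochs by default).
Evaluation accumulates per-class TP/FP/FN over the whole dataset and reports
per-class IoU `TP/(TP+FP+FN)` and their unweighted mean (MIoU), background
included. Classes absent from both prediction and truth contribute no term
(the only consistent reading when `TP+FP+FN = 0`).

## Where the architecture was genuinely open

The reference description of DCSAnet fixes parameter and FLOP budgets
(0.45 M / 17.00 G for the plain decoder, 0.57 M / 18.06 G for the full model
at 512×512) but not the channel widths, the decoder's internal structure, the
second branch kernel, the attention mechanism, or the FLOP-counting
convention. Those were resolved as follows, and
`scripts/calibrate_widths.R` documents the search:

* **Widths.** Stage widths are tied to the stem (each DCA-B doubles), so the
  encoder has one knob. Stem 6 (stages 12/24/96) plus decoder widths
  88/40/32/72/38 put both variants inside the printed budgets
  simultaneously: 0.463 M / 17.02 G (plain) and 0.557 M / 18.04 G (full).
* **Decoder depth.** A decoder that stops convolving at 1/4 scale cannot
  reach 17 GFLOPs at any width compatible with 0.45 M parameters — the
  printed budgets imply convolutional refinement at 1/2 and full resolution,
  as in the U-Net decoders this family of models borrows. The decoder
  therefore carries one convolution per upsampling step (1×1 at 1/16 where it
  only squeezes channels, 3×3 elsewhere).
* **Guided aggregation placement.** Transforming the guide at its native 1/32
  resolution would make the guided path nearly free (~0.1 G), which
  contradicts the printed 1.06 G gap between the plain and full models.
  Refining the guide at the decoder's 1/8 working resolution reproduces both
  the parameter gap (+0.094 M vs printed +0.12 M) and the FLOP gap
  (+1.02 G vs printed +1.06 G), so that reading was adopted.
* **Branch kernels.** The ablation knob names one kernel per model (5×1, 7×1,
  9×1); the second branch uses the smallest odd kernel (3) so the pair stays
  multiscale at minimal cost. Both are configurable.
* **Attention.** Realized as squeeze-and-excitation (global average pool →
  bottleneck with reduction 4 → sigmoid gate). It sits on the projected `C`
  width rather than the expanded `4C` width: on `4C` it would cost `8C²`
  parameters per block (~0.3 M at the calibrated widths), overshooting the
  parameter budget by itself.
* **FLOPs convention.** `model_summary()` counts FLOPs = 2 × multiply-
  accumulates over convolution and dense layers only (normalization,
  activations, pooling, resizing and elementwise ops excluded). Counting
  MACs as 1 FLOP would halve the totals to ~8.5 G, far from the printed
  17–18 G, so the 2× convention is used throughout. `conv_flops()` itself
  returns the raw closed-form MAC counts.
* **Known inconsistencies.** The source tables also contain rows that no
  parameter accounting can reproduce (a 9×1 model smaller than a 7×1 model;
  a parameter change when the parameter-free shuffle is removed). These rows
  are not calibration targets; in this implementation parameters are
  monotonically nondecreasing in `kernel_N` by construction.

## Numerical engine

No deep-learning framework is required: the package ships a compact
reverse-mode autodifferentiation engine on dense matrices. Feature maps are
`(B·H·W) × C` matrices; convolutions are per-tap gathers followed by matrix
products (BLAS), depthwise convolutions are per-tap broadcast products,
bilinear resizing is a cached sparse operator, and batch normalization uses
batch statistics in training and running moments (momentum 0.1, eps 1e-5) at
inference. Weights are He-initialised; biases exist only where no
normalization follows (the classifier and the attention bottleneck). All
randomness (initialisation, shuffling, augmentation, scene synthesis) is
seeded, and two runs with the same seeds produce identical loss histories.
Gradient correctness is tested against central finite differences per
operation and end-to-end.

Degenerate shapes worth knowing about: inputs must be divisible by 32 (the
deepest downsampling); DCA-B rejects odd spatial sizes rather than padding
silently; and a 1×1 `feat3` with batch size 1 makes batch normalization
constant (its batch variance is zero), which legitimately stops gradient flow
— train with inputs of at least 64×64 or batches of several images.

## The synthetic scenes, and what passing them means

Real field imagery for this task is not public, so the package generates
scenes that copy the *geometry* of the dataset it emulates: a noise-textured
brown soil background with low-frequency shading; soybean as clusters of
three elliptical leaflets; graminoid weeds as thin curved strokes (2–5 px
wide); broadleaf weeds as broad lobed blobs; objects drawn until per-class
pixel-fraction targets are met (defaults 0.20/0.08/0.10, within ±0.05), with
a configurable fraction of deliberate overlaps where the later-drawn class
owns the pixels. Grass strokes deliberately share the soybean hue so the two
green classes cannot be separated by colour alone — shape must be learned,
mirroring the real grass/crop confusion this architecture targets. Broadleaf
is a distinct darker blue-green.

The generator does *not* emulate photorealistic texture, lighting, leaf
venation, specularity, annotation noise, or scale variation from camera
height. Passing the learnability test therefore shows that the architecture,
loss, optimiser and metrics are wired correctly and can fit structured
multi-class scenes — not that the originally reported field accuracy (MIoU ~0.86 on
real imagery) is reproduced. That number requires the original non-public
dataset and GPU-scale training and is out of scope here.

## Desk-scale test sizing

The test suite runs on one CPU, so problem sizes are chosen accordingly (all
of them package choices, recorded here): unit tests exercise blocks at
6–16 px tiles and a stem-2 model; the learnability check trains a stem-4
model (stage widths 8/16/64, decoder 16/16/16/12/12, ~0.22 M parameters) on
eight 128×128 scenes with Adam at lr 0.003, batch 4, early-stopping once
training MIoU ≥ 0.90 (checked every 10 epochs, cap 300). The raised learning
rate relative to the 0.001 default is a deliberate desk-scale choice: with
only eight images per epoch the batch gradient is smooth and the higher rate
roughly halves time-to-criterion (~130 epochs, about 4 minutes). The
full-size cost figures (the reference budgets) involve no training at all —
`model_summary()` is analytic.

## Limitations

* Training in plain R is CPU-bound and practical up to roughly 10⁵-parameter
  models on ~10² small images; the full 0.56 M model at 512×512 is
  *buildable* and *measurable* but not trainable in reasonable desk time.
* Class imbalance is handled only by the plain cross-entropy of the original
  recipe; no class weighting or focal loss.
* Rotation augmentation is restricted to right angles (keeps the square frame
  without border fill; the source recipe does not state its angles).
* The LabelMe reader accepts polygons only (no circles/rectangles dialects).
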