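---
title: "Quantifying stomatal dynamics from microscope video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stomatal dynamics from microscope video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomatrack)
```

## The problem

Stomata — the pores on the leaf epidermis bounded by two guard cells — regulate
gas exchange and transpiration. Their behaviour is often *patchy*: neighbouring
stomata on the same leaf can open and close differently, which static snapshots
cannot capture. Time-lapse microscope video of a fixed leaf patch can, but only
if the analysis is automated: each selected stoma must be located in every
frame, the open aperture inside it segmented, and the aperture pixel count
(the stomatal opening area, SOA) turned into a per-stoma time series.

`stomatrack` implements that pipeline in three stages:

1. **Tracking** — one kernelized correlation filter (KCF) per stoma follows
   the selected rectangle through the sampled frames.
2. **Segmentation** — a UNet-style encoder–decoder with a depthwise-separable
   (MobileNet-style) encoder and four squeeze-and-excitation (SE) attention
   blocks labels every pixel of each tracked crop as background or open
   aperture.
3. **Quantification** — SOA time series, smoothed first-derivative closure
   rates, cross-stoma summaries, and Pearson correlations with gas-exchange
   logs (Pn, Ci, Gs, Tr).

A synthetic scene generator renders ground-truthed videos so that every stage
is testable end-to-end without any real recordings.

## The tracking model

Stomata are effectively immovable under a fixed microscope: only the aperture
size changes. This makes a classical correlation-filter tracker the right
tool — no training data, deterministic, and fast. The KCF trains a ridge
regression over all cyclic shifts of a padded, cosine-windowed grayscale
template against a centred Gaussian response; the kernel trick (a Gaussian
kernel here) and the circulant structure let both training and detection run
in the frequency domain:

- training: $\hat\alpha = \hat y / (\hat k^{xx} + \lambda)$
- detection: $f(z) = \mathcal{F}^{-1}(\hat k^{xz} \odot \hat\alpha)$,
  with the box moved to the integer argmax of $f$.

Hyperparameters (exposed in `kcf_params()`): padding 1.5, Gaussian kernel
bandwidth $\sigma = 0.2$, regularization $\lambda = 10^{-4}$, model
interpolation $\eta = 0.075$; the regression target bandwidth is 0.1 of the
target size, the standard setting for this tracker family. Two numerical
choices matter:

- Each patch is standardized (zero mean, unit variance) before windowing.
  The kernel bandwidth is therefore relative to standardized inner products,
  which keeps the kernel spectrum well conditioned — without this, the ridge
  denominator can pass arbitrarily close to zero on low-contrast microscopy
  patches and the response map degenerates into ringing.
- Peak localization is integer argmax with ties broken at the smallest
  row-major index; no sub-pixel interpolation. Stationary targets do not need
  it, and determinism is worth more than fractional accuracy here.

There is no scale adaptation: the box footprint is fixed at initialization,
because a stoma's outline does not change — only its interior aperture does.

## The segmentation network

The encoder is a MobileNet-v1-style stack: a strided standard convolution
followed by depthwise separable blocks (per-channel $3\times3$ depthwise
filtering, then $1\times1$ pointwise mixing). A $k\times k$ separable stage
costs $k^2 C_{in} + C_{in} C_{out}$ weights against $k^2 C_{in} C_{out}$ for
the standard convolution — a ratio of exactly $1/C_{out} + 1/k^2$. Four
intermediate features f1–f4 are taken at 1/2, 1/4, 1/8 and 1/16 resolution.

Each skip feature passes through one SE block (global-average squeeze, ReLU
bottleneck with reduction $r = 16$, logistic gate, per-channel rescale) before
decoder concatenation — four SE blocks in total. The exact placement inside
the UNet is a genuinely open design point; gating the skip features is the
most common embedding and is what we use. The decoder upsamples bilinearly
($2\times$, then a convolution, avoiding the checkerboard artifacts of
transposed convolutions), concatenates the gated skip, and finishes with a
$1\times1$ head and per-pixel softmax. Any input whose sides are divisible by
16 produces a same-size mask.

Training follows the published recipe where stated: He initialization, Adam
at learning rate 0.001, batch size 5, per-pixel categorical cross-entropy
(the loss itself is unstated in the source material; cross-entropy is the
default for softmax heads). Intensity normalization is a plain division by
255 onto $[0,1]$. Epochs default to 100 with optional early stopping on a
held-out split. Inference resizes a crop of any size to the configured input
(416×416 by default), takes the per-pixel argmax with ties resolved to
background, and resizes the mask back to the crop's native size with
nearest-neighbour sampling so that areas are counted at native resolution and
stay comparable across crop sizes.

The whole network — convolutions, SE blocks, bilinear resampling, softmax,
reverse-mode gradients, Adam — is implemented in this package (C++ kernels
for the convolutions, an explicit backward tape in R). The gradients are
validated against central finite differences in the test suite, and the
separable convolution against a brute-force nested-loop oracle. Transfer
learning (a pretrained encoder) is intentionally not a default: the package
must be fully reproducible offline.

## Augmentation

The training-set expansion applies, independently per pair: rotation up to
±25° with probability 0.80, left-right flip with probability 0.50, and
scaling to 0.85× with probability 0.30 — the published recipe. Both members
of an image/mask pair receive the identical geometric transform: bilinear
interpolation with reflection fill for the image, nearest-neighbour with zero
fill for the mask, so masks remain strictly 2-valued and foreground counts
change only through geometry, never interpolation blur. Scaling is
implemented as shrink-then-pad back to the original size. Reflection fill
(rather than black corners the model could shortcut on) is our choice; the
published recipe does not state a fill rule, and the image-processing
packages available do not offer reflective fills for rotation, so the affine
sampler is implemented here.

## Metrics

From pooled (micro-aggregated) confusion counts: pixel accuracy PA, per-class
pixel accuracy CPA, MPA = mean(CPA), per-class IoU and MIoU = mean(IoU).
Micro-aggregation matches the "ratio of correct pixels to total pixels"
definitions; whether the published numbers pooled pixels or averaged
per-image is not stated, but the MPA = mean(CPA) identity holds either way.
A class with no ground-truth pixels has an undefined CPA (likewise IoU for an
empty union); such classes are reported `NA` and excluded from the means
rather than forced to an arbitrary 0 or 1. For every class IoU ≤ CPA, hence
MIoU ≤ MPA whenever the same classes enter both means.

## The synthetic scene generator

Each scene renders stationary stomata as a bright elliptical guard-cell rim
with a dark elliptical aperture, on a band-limited texture (blurred white
noise) standing in for epidermal relief, plus per-frame Gaussian sensor noise
and a slow linear illumination ramp. Masks are rasterized by centre-of-pixel
inclusion so ground truth stays integer-valued; the rasterized area agrees
with the analytic $\pi a b$ within 2% whenever both semi-axes are ≥ 4 px.
Aperture kinetics are programmable: constant, linear, or logistic closure
$A(t) = A_{end} + (A_0 - A_{end})/(1 + e^{k(t - t_0)})$, whose closure rate
is fastest at $t_0$.

Defaults encode the recording conditions the pipeline targets: 640×480 frames
at 20 fps. Stomatal size in pixels at the study's magnification is not
published, so the generator's geometry is a free parameter; defaults (guard
semi-axes ≈ 26×16 px, apertures up to ≈ 14×7 px) give apertures of a few
hundred px², comfortably above the segmentation resolution limit. The
chilling-stress demo scene (`scene_chilling_demo()`) uses three stomata with
$(k, t_0)$ = (0.08, 120), (0.05, 210), (0.03, 300) — faster closers close
earlier, all essentially closed within the 10-minute window, mirroring the
patchy fast/slow closure reported under chilling.

What the generator does *not* emulate: real guard-cell biomechanics, focus
drift, specular highlights, overlapping structures, or pathogen bodies
(powdery mildew is a known failure mode of aperture segmentation in the
field). Passing the synthetic benchmarks therefore demonstrates that the
algorithms are implemented correctly and that the pipeline is internally
consistent — not that the shipped defaults would reach any particular
accuracy on real leaf recordings, which require retraining on annotated
microscope data.

## Desk-scale study conditions

The test suite and the acceptance script exercise two trained models:

- a *benchmark* model — width-multiplier 0.25, trained at native 64×64 input
  on 50 generator crops (a fifth of them fully closed, so the closure
  endpoint is in-distribution) and evaluated on 20 held-out crops; and
- the *reference pipeline* model (`train_synthetic_segnet()`) — the same
  width, 150 crops, but supervised at a 128×128 input, i.e. every crop is
  lifted 2× through the identical resize path that inference uses.

The 2× input matters for area accuracy, not for IoU: the encoder's finest
features sit at half the input resolution, so a model working at native
resolution quantizes its aperture boundary at roughly the native pixel
pitch. That is invisible on large apertures but fatal for small ones — a
half-pixel boundary bias on a 100 px² aperture is a ~20% area error. Lifting
the input 2× puts the decision grid at native pitch, roughly halving that
bias; the acceptance script measures the resulting worst-frame SOA recovery
error on the closure scene. The same logic is why a fixed large network
input (416×416) is the natural test protocol for variable-size crops.

The end-to-end run samples the 600 s closure scene at 0.1 fps (60 frames of
192×144 px, three tracked 64×64 boxes). These sizes were chosen once so that
a complete from-scratch run — training included — finishes in minutes on one
CPU core while still exercising every stage at realistic geometry; they are
stated here as the package's reference conditions for its own benchmarks.

## Quantification choices

- SOA is counted on masks at the crop's native resolution, never at the
  network's input resolution.
- Closure-rate curves apply a 5-sample moving average before central finite
  differences (one-sided at the ends); raw finite differences of integer
  pixel counts are dominated by quantization noise. The window is
  configurable.
- For correlations with gas exchange, the mean SOA series is linearly
  interpolated onto the instrument's 30-s grid (the coarser, authoritative
  clock), and the coefficient is Pearson's r, reported with the number of
  overlapping samples. Zero-variance inputs yield `NA` with a warning rather
  than a fabricated value.

## Known limitations

- The AVI support is deliberately minimal: uncompressed 24-bit RGB only.
  Compressed recordings should be transcoded or exported as an image
  sequence, which is also the only bit-stable dialect across platforms.
- The tracker does not re-detect after occlusion and does not adapt scale;
  both are out of scope for stationary stomata.
- The shipped training path uses synthetic data only. Real deployments
  should train on annotated crops from their own microscope with
  `train_segnet()`; the architecture and recipe carry over unchanged.
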