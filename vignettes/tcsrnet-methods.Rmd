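---
title: "TCSRNet: model, profiler calibration, and synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TCSRNet: model, profiler calibration, and synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tcsrnet)
```

## The problem and the model

Flue-curing dehydrates harvested tobacco leaves over roughly a week, and
practice divides the process into ten visually defined stages: leaves first
yellow (stages 1–4), then dry from about 30% to fully dry (stages 4–10),
with the main veins whitening late in the process. Automating stage
recognition inside a curing barn means classifying RGB images on very
constrained hardware, so the model of interest, TCSRNet, is a lightweight
CNN: a MobileNetV3-Small skeleton whose inverted-residual blocks are
modified in three ways.

**Inception expansion.** The 1×1 expansion convolution at the head of each
inverted-residual block is replaced by four parallel branches — 1×1
convolution, 3×3 convolution, 3×3 dilated convolution (dilation 2,
effective receptive field 5×5), and a 3×3 max-pool pass-through — each
followed by its activation (the three convolutional branches also carry
batch normalisation), concatenated along channels, and fused/expanded to
the block's expansion width by a 1×1 Ghost convolution.

**Ghost convolutions.** A Ghost convolution produces `m = n/s` intrinsic
maps with a standard (here 1×1) convolution and derives the remaining
`(s-1)·m` "ghost" maps from them with cheap depthwise `d×d` filters. The
parameter ratio against a standard convolution is

$$r_c = \frac{n\,c\,k^2}{\frac{n}{s}\,c\,k^2 + (s-1)\frac{n}{s}\,d^2},$$

which collapses to `s·c/(c+s-1) → s` when `k = d`. Ghost convolutions fuse
the Inception branches and perform the block's linear projection.

**MAAM.** The Multi-scale Adaptive Attention Module computes a per-channel
descriptor (spatial average + maximum + population standard deviation,
added elementwise) and a per-position descriptor (the same statistics
across channels), maps them through a bottlenecked two-layer transform
(channel path) and a 1×1 convolution (spatial path) with sigmoid outputs
`A_c` and `A_s`, and blends them with an input-dependent scalar gate
`g = sigmoid(w·GAP(x) + b)`:

$$y = x \odot \left(g\,A_c \oplus (1-g)\,A_s\right).$$

MAAM replaces Squeeze-and-Excitation wherever the baseline had it (an
option re-enables it on the two SE-free blocks). At `g → 1` the module is
pure channel attention, at `g → 0` pure spatial attention; a constant
feature map contributes exactly zero through the standard-deviation
pooling.

## Free hyperparameters and the complexity calibration

The published architecture fixes the block schedule but not every internal
width, so four hyperparameters remain free and are centralised in the
model config:

* **Ghost ratio `s`** (default 2) and cheap-kernel `d` (default 3) — the
  canonical Ghost design values.
* **MAAM reduction `r`** (default 12): the channel bottleneck is
  `make_divisible(C/r, 8)`, the same rounding rule SE uses.
* **Inception branch widths**: a factor on the block's input channels per
  feature-map resolution stage, shipped as 11/8 (56 px), 1 (28 px),
  3/4 (14 px) and 7/8 (7 px). Scaling widths per stage — wider where maps
  are large and informative, narrower where channel counts already
  dominate — is the usual Inception-family practice.

These defaults were chosen by `calibrate_defaults()`: a reproducible grid
search that profiles the full model at 224×224 and ranks grid points
lexicographically — first the parameter distance to the published 1.749M
budget beyond its printed precision (parameters are exact,
convention-free counts), then the FLOP distance to 158.136M. The shipped
combination reproduces the parameter budget exactly at three decimals
(1,749,069 parameters) and lands within 0.04% of the published FLOPs.

Two contract details follow from the same calibration. The max-pool branch
of the Inception expansion is parameter-free (max-pool + activation, no
affine normalisation), the literal reading of a weightless pass-through
branch. And only blocks that have an expansion stage receive the Inception
substitution and the Ghost projection; the first bottleneck (expansion
factor 1) has no expansion convolution to replace and keeps its original
form.

## The FLOP-counting convention

Papers rarely state their FLOP counter, and counters disagree about
multiply-accumulates versus two-operation counting and about whether
normalisation, activations and pooling are charged. The profiler therefore
fixes one convention and documents it in every report:

* one multiply-accumulate = one FLOP (convolutions and linear layers);
* bias additions 1/element; batch normalisation 2/element (scale, shift);
* ReLU, sigmoid, hard-sigmoid 1/element; hard-swish 2/element (the clipped
  shift and the product);
* pooling 1 per input element (including each statistical-pooling pass in
  MAAM and SE's global pool);
* elementwise products and additions (attention re-weighting, residual
  additions, the gated fusion) 1/element.

The convention was pinned by profiling the unmodified MobileNetV3-Small
baseline against its published 61.177 MFLOPs — the profiled value is
61.050M, within 0.21%; counting two operations per multiply-accumulate
would roughly double the number, so the published figures are MAC-style
counts — and then frozen for every other model. Parameters count every
learnable array (convolution and linear weights and biases, normalisation
scale and shift) and exclude running statistics; the analytic per-layer
breakdown is tested for equality against direct enumeration of the weight
arrays on every preset.

## Network internals and numerical choices

The whole forward/backward stack is implemented in base R on BLAS matrix
products (im2col for dense convolutions, shift-and-add for depthwise
convolutions and pooling), with every layer's reverse pass verified by
central finite differences in the test suite. Choices worth recording:

* **Normalisation statistics.** Training proceeds image by image
  (single-image batches). Per-image statistics would make batch
  normalisation an instance normalisation, which removes exactly the
  image-level colour shifts that separate the curing stages, and makes
  `GAP(BN(x))` a constant. The package therefore normalises with
  exponentially tracked population statistics: a short warm-up (three
  passes over up to 32 training images, momentum 0.1) lets each layer's
  tracked mean/variance converge to the activation distribution induced by
  the already-converged statistics of the layers before it, after which the
  statistics are frozen so the training objective is stationary. Inference
  uses the same statistics, so training and evaluation behave identically.
* **Initialisation.** He-normal weights; unit scale, zero shift for
  normalisation; the classifier's weight matrix is scaled by 0.1 so initial
  logits are near zero and the first loss sits at `log K`.
* **Optimisation.** Cross-entropy with Adam (β₁ 0.9, β₂ 0.999), cosine
  learning-rate decay, and global gradient-norm clipping at 5 — the small
  gradient-accumulation batches otherwise make the first steps unstable.
  The shipped defaults (100 epochs, batch 32, base rate 1e-3) describe the
  full-scale protocol; the desk-scale runs in the tests pass their own
  smaller values.
* **Ties and degenerate inputs.** Max-pooling and the max-pooling
  descriptors break ties towards the first (column-major) element; the
  standard-deviation pooling carries a 1e-12 epsilon inside the square
  root, so a constant map contributes ~1e-6 rather than an undefined
  gradient; degenerate precision/recall ratios (empty denominators) are
  defined as 0 so macro means stay total; checkpoint selection takes the
  highest validation accuracy with ties towards the earliest epoch.
* **Input sizes.** The stem and the four stride-2 blocks downsample 32×,
  so inputs must be multiples of 32; 224 is the reference size for
  profiling and 64 the desk-scale training size.

## The synthetic study design

No public curing-stage corpus is deposited, so the package carries a
renderer that is the canonical fixture for every pipeline test. It encodes
only the quantified stage parameters — yellowing fraction (0.3, 0.7, ~1, 1
over stages 1–4), drying fraction (0.3, 0.5, 0.7, 0.9 over stages 4–7,
reaching 1 at stage 10), vein whiteness rising late, curl increasing — as
an elliptical leaf whose hue interpolates green → yellow → brown, with
drying-driven desaturation, brown speckle and contour shrink, whitened
main/lateral veins, and barn-imaging artefacts (lighting gradient,
steam-like Gaussian blur, sensor noise). The dry/wet-bulb temperatures of
the stage standard ride along as metadata and are not rendered.

The generator defines the desk-scale study conditions: 50 images per stage
at 224×224, stages 1 versus 10, an 80/20 split, five epochs at input 64.
Under those conditions the full TCSRNet trains to ≥90% validation
accuracy on one CPU — the acceptance surface for the training loop. The
renderer is deliberately not biologically calibrated: passing these tests
shows that the architecture, gradients, pipeline and checkpoint selection
work, and that the generator encodes a learnable stage signal; it says
nothing about accuracy on real curing-barn imagery, which the published
90.35% describes. Augmentation (geometric, filtering and colour families,
stacked `compose_depth` at a time) is applied to training data only.

## Known limitations

* Pure-R training is desk-scale: minutes for a hundred 64-pixel images,
  not hours of GPU throughput; the full-protocol defaults are provided but
  impractical without porting the kernels.
* Single-image batches with frozen statistics are a deliberate departure
  from mini-batch batch normalisation; at full scale the usual batch
  semantics would be preferable.
* The Inception branch widths, MAAM bottleneck and gate parameterisation
  are calibrated reconstructions of internals the publication does not
  fully specify; the complexity budget pins them jointly, not uniquely.
* Attention placement follows SE placement exactly by default; whether the
  two SE-free blocks should also carry MAAM is unknowable from the text
  (`attention_everywhere` exposes the alternative).
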