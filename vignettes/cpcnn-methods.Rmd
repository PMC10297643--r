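---
title: "Cascaded-progressive networks for meniscus-injury detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded-progressive networks for meniscus-injury detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

On sagittal T2 knee MRI the meniscus appears as a dark (low-signal) triangular
or bow-tie structure; a tear shows up as a thin bright streak inside it. The
diagnostic question is binary — injured or not — but a clinically useful
classifier should also *show* where it thinks the lesion is, from image-level
labels alone (weak supervision: no pixel masks are ever used in training).

`cpcnn` implements a cascaded-progressive convolutional network (C-PCNN) for
this task: three residual-network tiers look at the same scene at three
resolutions (nominal 640x320, 1280x640 and 2560x1280 pixels), the
low-resolution tier produces a Grad-CAM lesion localization map, and a lesion
attention module (LAM) uses that map to re-weight the high-resolution features
before the final classification head.

## Model

### Backbone tiers

All tiers are built from ResNet50 vocabulary: a 7x7/stride-2 convolution with
3x3/stride-2 max-pool (`conv_1`), bottleneck residual blocks with channel
triplets (64,64,256), (128,128,512), (256,256,1024), (512,512,2048)
(`block_1..4`, repeats 3/4/6/3 at full scale), and, where present, a head of
global average pooling, a 2-unit linear layer and softmax (`fc`). The tier
layouts are

* primary (low resolution): `conv_1, block_1..4, fc`
* secondary (mid): `conv_1, block_1, block_2`
* tertiary (high): `conv_1, conv_2, block_1..4, fc`

`conv_2` (3x3, 64 channels, stride 2) halves the tertiary maps so that the
secondary and tertiary `block_2` taps have identical shape — the invariant
that makes the second fusion point well-defined. Every stride-2 stage maps a
spatial extent $n$ to $\lceil n/2\rceil$, so tap shapes follow closed-form
arithmetic that the test-suite checks independently.

Batch normalization follows every convolution (the standard ResNet recipe);
inputs are single-channel, and no pretrained weights are used anywhere — with
grayscale medical images and a fully synthetic training corpus there is
nothing for ImageNet weights to transfer to, and channel replication would
triple the first-layer cost for no benefit.

### Weakly supervised localization

For an input image $I$ at the low level, the hooked feature map $f_i$ is the
output of the third convolution of the first residual unit of `block_3`
(1024 channels at full width; the hook is configurable). With $y^c$ the logit
of class $c$, the channel weights and the map are

$$\alpha_i = \mathrm{GAP}\!\left(\frac{\partial y^c}{\partial f_i}\right),
\qquad
L = \mathrm{ReLU}\Big(\sum_i \alpha_i f_i\Big),$$

i.e. classic Grad-CAM: gradients are spatially averaged into per-channel
weights, and the rectified weighted sum is the evidence map. The map is
computed for the injury class during training-time map generation and for the
predicted class at inference. It is upsampled bilinearly to the low-level
image size and normalized to $[0,1]$ by its maximum; an all-zero map stays
zero rather than dividing by zero.

### Lesion attention module

The LAM consumes the lower-tier features $x_l$, the (fused) higher-tier
features $x_h$ and the localization map $L$, and produces re-weighted
high-resolution features:

* **feature attention** $A = HW \cdot
  \mathrm{softmax}_{\text{positions}}\big(w^\top(T_l x_l + T_h x_h)\big)$,
  where $T_l, T_h$ are learned 1x1 convolutions to a common width and $w$ a
  1x1 convolution to one channel. The softmax runs over all spatial
  positions; the $HW$ rescale keeps the mean weight at 1 — without it the
  attention mass would shrink as maps grow and the identity limit below would
  be unreachable.
* **location attention** $M = 1 + \mathrm{resize}(L)$. The shift by one is a
  deliberate design choice: multiplying by $L$ alone would zero out every
  non-lesion feature and destroy the classification of normal knees, whereas
  $1 + L$ leaves non-lesion positions at identity weight and amplifies the
  lesion region up to 2x.
* **output** $\tilde{x}_h = T_o(x_h)\odot A \odot M$ with $T_o$ a 1x1
  convolution initialized at identity, so an untrained LAM passes the high
  features through unchanged (the identity limit: zero map and uniform
  attention recover a pure linear transform of $x_h$).

### The cascade

The primary `block_1` tap is bilinearly upsampled and added to the secondary
`block_1` output; the secondary `block_2` tap is added to the tertiary
`block_2` output (equal shapes thanks to `conv_2`); the LAM then re-weights
the fused features with the localization map resized to that tap, and the
result feeds tertiary `block_3`. The tertiary `fc` head gives the final
diagnosis; the decision threshold is 0.5 with ties classified positive
(deterministic and documented). Fusion is element-wise addition — with equal
channel counts at both fusion points, addition needs no extra parameters and
keeps gradient flow symmetric; pooling the larger map instead would discard
exactly the high-resolution detail the cascade exists to exploit.

An optional supervised auxiliary head on the secondary `block_2` tap can be
enabled (`auxSecondaryHead`); it is off by default because the secondary tier
has no `fc` in the published layout and the cascade trains well without it.

## Training

Training is two-stage:

1. **Stage 1** trains the primary tier alone with cross-entropy on image
   labels.
2. The primary tier is frozen and its Grad-CAM map is computed once per
   training case (injury class). **Stage 2** trains the secondary and
   tertiary tiers plus the LAM with
   $\lambda_{\text{primary}}\,\mathrm{CE}(\text{primary})
   [\text{frozen, reported only}] + \lambda_{\text{final}}\,
   \mathrm{CE}(\text{tertiary})$.

The split is forced by the map itself: training end-to-end *through* the
Grad-CAM backward pass would require second-order gradients, and the map is
only meaningful once the primary classifier is. Freezing also lets the maps
be cached, which dominates the stage-2 cost otherwise.

The optimizer is SGD with momentum 0.9 and cosine-decayed learning rate
(default 0.01), batch size 8. The cascade stage additionally clips the global
L2 gradient norm at 5: the position-softmax can concentrate the attention
mass onto a few positions early in training, and the resulting activation
spikes occasionally destabilized the cascade loss; clipping removes those
excursions without affecting well-scaled steps. Stage 1 is a plain classifier
and trains unclipped. Non-finite losses abort with a diagnostic rather than
training onward silently.

Every random draw — initialization, batch shuffling, phantom geometry — flows
through per-purpose streams derived from one seed, so a training run is
bit-reproducible and any single phantom case can be regenerated in isolation.

## The phantom generator

No public dataset of labelled sagittal knee MRIs exists for this task, so the
package ships a synthetic generator that emulates the features the method
actually exploits:

* a bright noisy background (mean 0.5, Gaussian texture sd 0.06, clipped to
  $[0,1]$);
* one or two dark triangular meniscus horns (intensity 0.18) with per-vertex
  jitter — two mirrored triangles form the bow-tie appearance of mid-joint
  sagittal slices;
* for injured cases, a thin bright streak (intensity 0.85, 2 px thick at base
  resolution) strictly inside one horn, drawn as an anti-aliased segment
  along a random chord and clipped so streak plus a guard ring stay inside
  the triangle; the hosting horn gives the anterior/posterior tag and the
  rasterized streak gives the pixel mask.

Intensities were chosen once to mirror the qualitative contrast of
fat-suppressed T2 images (dark meniscus on bright-ish background, fluid-bright
tear) at a healthy contrast-to-noise ratio; the 50% injury rate mirrors a
balanced case-control corpus. Geometry is defined in base-pixel coordinates
and re-rasterized analytically at each pyramid level, and the noise texture is
drawn at base resolution and upsampled, so all three levels depict the same
scene — the streak stays thin and bright at every level instead of being
blurred by resampling.

What the phantom deliberately does **not** model: MR physics (bias fields,
coil profiles, partial-volume effects), anatomy other than the horns,
3-D continuity across slices, and tear-direction morphology. Passing the
recovery study therefore shows that the cascade, localization and attention
machinery are wired correctly and can learn the intended cue — not that the
method reaches any particular clinical accuracy.

## Numerical choices

* All resampling is bilinear with half-pixel centers and edge clamping;
  constants are preserved exactly and the map is linear, so its adjoint is
  used in backpropagation.
* Softmax is computed max-shifted; cross-entropy clamps probabilities at
  1e-12.
* Localization scoring: the map is upsampled to the mask resolution, the
  argmax breaks ties at the first column-major index, and a hit requires the
  peak within a 9 px Euclidean dilation of the mask.
* Metrics with empty denominators are reported as missing and flagged, never
  coerced to 0; report display rounds half away from zero to 4 decimals.
* ROC ties collapse into diagonal segments and trapezoidal integration makes
  the AUC equal the Mann-Whitney statistic with half-credit ties.
* Stratified folds deal shuffled cases round-robin with a running fold
  pointer, so fold sizes differ by at most one overall *and* per class;
  1396 cases split 280/279/279/279/279.

## Problem sizes

The tiny preset (quarter-width backbone, single-unit blocks, 160x80 base
pyramid, 8 + 4 epochs) is the package's desk-scale configuration: one full
recovery study — 200 training phantoms, 100 held-out — trains in a few
minutes on one CPU core in double precision. The full-scale configuration
(640x320 base, full ResNet50 widths) is the same code path and is exercised
shape-wise in the tests.

## Known limitations

* The localization map inherits the hook tap's resolution (native 40x20 at
  full scale, 5x10 at the tiny preset). The argmax of a bilinearly upsampled
  map always lands on a native cell position, so peak placement is quantized
  to roughly one cell; with 16 px cells this is the dominant error source in
  the peak-in-dilated-mask score, and localization quality varies noticeably
  across training seeds.
* The published description of the "improved" Grad-CAM head (an extra
  convolution + GAP + softmax appended to the network) is not fully
  specified; the package implements standard Grad-CAM at the stated hook.
* Stage 2 never updates the primary tier, so cascade training cannot repair
  a poorly localized primary map — by design, at the cost of end-to-end
  optimality.
* Everything is desk-scale CPU code: double precision, single-threaded BLAS
  convolutions. It is meant for method study and testing, not for training
  on clinical volumes.
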