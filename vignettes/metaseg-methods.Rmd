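---
title: "Few-shot volumetric segmentation with metaseg: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot volumetric segmentation with metaseg: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metaseg)
```

## The problem

Organ segmentation models trained on one anatomical structure transfer
poorly to another, and annotated 3D medical images are expensive: a new
target organ often comes with five or ten labelled CT volumes, not five
hundred. `metaseg` addresses this few-shot regime with **model-agnostic
meta-learning (MAML)** wrapped around an **enhanced residual 3D U-Net**.
Meta-training treats each organ as a *task* and learns an initialization
$\theta$ that adapts to a new task in a few gradient steps; meta-testing
fine-tunes $\theta$ on the $k \in \{5, 10\}$ labelled shots of a held-out
task; final testing evaluates the tuned model on unseen volumes of that
task with Dice, IoU and the 95th-percentile Hausdorff distance.

## The model

### Backbone

The segmentation network is a five-level residual 3D U-Net:

* **Encoder**: each level is a residual unit — two $3^3$
  convolution + normalization + PReLU blocks plus an identity/projection
  skip — whose first convolution carries stride 2, replacing pooling.
* **Decoder**: stride-2 transpose convolutions followed by a one-block
  residual unit, with skip connections concatenated from the matching
  encoder level.
* Channels double per level (16, 32, 64, 128, 256), one input channel
  (CT), two output channels (background/foreground logits), dropout 0.1,
  one learned PReLU slope per activation layer.

This configuration has exactly **4,808,917** learnable parameters, which
pins down every reconstruction choice the architecture description leaves
open (channel widths, level count, residual-unit count, kernel sizes, and
the fact that the normalization layers carry learnable scale and shift).
`count_parameters(build_backbone(backbone_config(), 1))` reproduces the
count, and the test suite cross-checks it against an independent
per-layer enumeration.

**Instance vs batch normalization.** The backbone description is
ambiguous: residual enhanced U-Nets are defined with instance
normalization, while the training section reports batch normalization.
With the batch size of 1 used throughout, the two normalize identically
(each sample's feature maps per channel), and their learnable-parameter
counts agree. `metaseg` defaults to affine instance normalization and
exposes `norm = "batch"` as a config switch; numerically both are the
per-sample, per-channel standardization.

**Dropout placement** is unstated beyond the rate; we apply it inside
every convolution block in the reference norm → dropout → activation
order. Parameter counts are unaffected either way.

### MAML

For tasks $T_i$ with support/query episodes, the inner loop adapts
$\theta_i' = \theta - \alpha \nabla_\theta L_{T_i}(f_\theta)$ (plain
gradient descent on the mean support Dice loss, `inner_steps` times,
default 1), and the outer loop minimizes
$\sum_i L_{T_i}(f_{\theta_i'})$ over the query sets with Adam
(learning rate $\beta$, weight decay $10^{-5}$).

**Reading of $\beta$.** The hyperparameter table lists
$\beta = 10^{-6}$; the prose attaches it to Adam, where $10^{-6}$ would
be an atypical moment coefficient. We read $\beta$ as the outer-loop
learning rate, per the meta-learning algorithm's own notation, and keep
Adam's moments at their standard (0.9, 0.999).

**Second-order term.** Differentiating through $\theta_i'$ requires
Hessian-vector products $H_s v$ of the support loss. Rather than
implementing double backpropagation in the hand-written engine, `metaseg`
evaluates them by central finite differences of the support gradient,
with the probe step scaled as
$h = \varepsilon\,(1 + \lVert\theta\rVert)/\lVert v\rVert$
(`hvp_eps`, default $10^{-4}$). This is exact for quadratics and agrees
with full finite differences of the outer objective to better than
$10^{-6}$ relative on smooth test networks — far inside the $10^{-3}$
the test suite demands. `first_order = TRUE` drops the term entirely
(the standard first-order MAML approximation) and roughly halves the
cost; CPU-scale experiments in the tests use it.

### Training protocol

Each meta-epoch samples one support/query episode per meta-training task
(10/10 by default, drawn uniformly without replacement from that task's
episode pool), applies one outer Adam step, and then scores the current
$\theta$ by mean evaluation-set DSC per task. Early stopping monitors
that DSC with patience 20 (meta-training) and returns the best-scoring
checkpoint, not the last. Whether the published evaluation images were
scored per epoch or once at the end is unstated; we evaluate per epoch
because the training curves are plotted against epochs. Meta-test
fine-tuning is ordinary Dice-loss training on the $k$ shots (Adam,
learning rate `fine_tune_lr`, default $\alpha$; batch size 1; patience
10 on the mean shot loss), and the initial $\theta'$ itself is eligible
as the best checkpoint, so fine-tuning can never return something worse
than its own start on that criterion.

## Metrics

* DSC $= 2|P \cap G|/(|P|+|G|)$ and IoU $= |P \cap G|/|P \cup G|$, both
  defined as 1 when both masks are empty and 0 when exactly one is.
* **HD95**: the evaluated 95% Hausdorff distance is not defined in the
  source beyond its name. We use the convention of the standard medical
  evaluation stacks: extract boundary voxels (foreground with a
  background 6-neighbour; the outside counts as background), compute
  directed nearest-surface distances in millimetres both ways, pool the
  two directed sets, and take the 95th percentile with linear
  interpolation. Cases where either mask is empty are undefined,
  excluded from HD95 means, and counted in the report.
* Predictions binarize by argmax over the two logit channels
  (equivalently, foreground softmax probability > 0.5).

The training loss is the smoothed soft Dice
$1 - (2\sum pg + s)/(\sum p + \sum g + s)$ with $s = 10^{-5}$ on both
numerator and denominator (the constant is unstated in the source; this
is the common default and it is configurable).

## Preprocessing

CT intensities are clipped to $[-200, 200]$ HU and linearly rescaled to
$[0, 1]$. The source states the window but not the mapping; clip + min–max
rescale is the convention of the framework it builds on, and the
endpoints are arguments. Resizing uses trilinear interpolation for
images and nearest-neighbour for masks (preserving binarity exactly),
rescaling voxel spacing so physical extent is unchanged. The published
target grids ($128 \times 128 \times 256$ and $128^3$) are presets, not
hard-coded; desk-scale work uses $32^3$.

## The phantom generator

Real experiments used a public whole-body CT corpus and a small hospital
set; neither ships with this package. The `synthetic phantom` module
generates seeded stand-ins with the same *statistical structure*: four
task families (a large lobed blob, an elongated capsule, two lateralized
ellipsoids) with per-subject variation in size, position, orientation
and intensity; background ≈ −60 HU and foreground ≈ +60 HU levels with
per-render spread and voxel noise, so the windowed contrast (≈0.35 vs
≈0.65) resembles soft tissue. Foreground and background means differ by
at least two pooled standard deviations by construction, so every task
is learnable. Masks are guaranteed nonempty and strictly interior to a
one-voxel ring. The noise-robustness protocol adds Gaussian noise
(mean 0.0, sd 0.2) on the windowed scale *after* windowing, re-clipping
to $[0, 1]$ — whether the original corruption preceded or followed
windowing is unstated; post-windowing matches corrupting
already-preprocessed images.

**What a green test establishes — and what it does not.** Phantoms share
the task structure (one variable foreground structure per volume,
CT-like contrast, inter-subject variability) but none of the hard parts
of real CT: anatomy, partial-volume effects, scanner physics, pathology.
Passing the desk-scale few-shot comparison shows the *machinery* works —
meta-initialization transfers and adapts better than random
initialization under an identical budget — not that the published
absolute accuracies are reproduced. Those require the original data and
GPU-scale training and are out of scope here.

## Desk-scale experiment design

The acceptance-level experiment mirrors the published split table at
$32^3$: three meta-training families with 10/10/10
support/query/evaluation images, one held-out family with $k = 5$ shots
and 10 test images. Scaled-down choices, fixed before the comparisons
were run: a reduced backbone (channels 4–16, one residual unit),
first-order meta-gradients, outer learning rate $5\times10^{-3}$ with a
15–30 epoch cap and patience 5 (the published $10^{-6}$ over hundreds of
GPU epochs is impractical on one CPU), and a deliberately tight 6-epoch
fine-tuning budget — the few-shot regime is precisely the one where
adaptation speed matters, and an unlimited budget would let any
initialization eventually fit five shots. Meta-training runs once per
experiment (as in the original design); the five paired seeds vary the
shot draw, the dropout stream and the random-arm initialization.

## Numerical notes

* Convolutions are im2col + GEMM (C++ patch gather/scatter, BLAS
  multiply); gradients are hand-written layer adjoints, verified against
  central finite differences to $\sim 10^{-10}$ absolute.
* With strided down/up-sampling the network is shift-equivariant on the
  stride lattice only: a constant input yields logits constant within
  each stride-phase of the padding-free interior (the property the tests
  assert), not globally constant.
* All randomness flows from explicit seeds: initialization, episode
  sampling, dropout, phantom rendering. Two runs with the same resolved
  configuration are bitwise identical.
* NIfTI-1 I/O is implemented directly (no R NIfTI reader exists in this
  stack) and cross-validated against `nibabel`; masks round-trip as
  uint8, images as float64 by default.

## Limitations

* Binary (one-structure) segmentation only; no multi-label heads.
* The engine is CPU-oriented; the full $4.8$M-parameter backbone at
  $128^3$ is supported but slow without a GPU framework behind it.
* HD95 and empty-mask conventions follow the common evaluation stacks;
  other percentile or directed-distance conventions would shift absolute
  HD values.
* First-order meta-gradients are an approximation; second-order is exact
  up to the finite-difference Hessian-vector products described above.
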