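---
title: "PL-Net: progressive-learning segmentation — model, training and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PL-Net: progressive-learning segmentation — model, training and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plnet)
```

## The problem

Encoder–decoder networks with skip connections (the U-Net family) are the
workhorse of 2D medical image segmentation — skin lesions in dermoscopy,
cell nuclei in microscopy, cardiac structures in short-axis MRI. Most
variants improve accuracy by adding modules or widening the network.
PL-Net instead reuses a fixed budget of convolutional blocks *progressively*:

* **Internal progressive learning (IPL).** The encoder–decoder is traversed
  in `n_steps` complete passes ("steps"). Each block holds one 3×3
  convolution unit per step, and each pass feeds the previous pass's decoder
  features back into the encoder through *backward skip connections* (BSC).
  Later passes therefore see a larger effective receptive field and
  coarse-to-fine mixtures of semantics.
* **External progressive learning (EPL).** Two depth variants of the network
  ("stages") share their blocks. Stage 1 stops one level above the bottom
  and is trained first (coarse phase); stage 2 adds the deepest level and is
  then trained jointly with stage 1 (fine phase; nothing is frozen). At
  inference the stage pre-activations are fused with equal weight:
  `y = logistic(y¹ + y²)` for binary tasks, a softmax over the per-class
  sums otherwise. The per-stage sigmoid prediction layers are never
  materialized ("pruned heads"), only the 1×1 pre-activation maps.

## Architecture in detail

Levels are indexed `d = 1..L` (default `L = 5`) with channel widths
`ch = round(ocs * c(32, 64, 128, 256, 512))`, rounded half-up and clamped to
at least 1. `ocs` (output-channel scale) is the single width multiplier; the
reduced variant uses `ocs = 0.5`. The wiring, fixed once and used
everywhere:

* **Encoder, per step `s`:** level 1 convolves the concatenation
  `[image, B₁]`, where `B₁` is the previous pass's finest decoder output.
  Level `d ≥ 2` convolves `maxpool₂([enc_{d−1}, B_{d−1}])` — the encoder
  output one level above concatenated with the same-scale backward feature,
  then pooled. On the very first pass no backward features exist and the
  backward slot is zero-filled; an exact "pass-through" is impossible when
  the same convolution must serve every pass with one shape, and a zero
  slot is its faithful translation. At a stage boundary the backward
  features are the previous *stage's* final decoder outputs, which is how
  stage 2 consumes stage 1's coarse result.
* **Stage bottoms.** Stage 2's bottom (level `L`) is a small block:
  an entry conv lifting `ch[L−1]` to `ch[L]`, the pass's step conv
  (`ch[L] → ch[L]`), and a shared refinement conv. It takes the plain
  pooled encoder feature — the bottom has no previous-pass decoder
  counterpart that exists in every stage, so no backward slot. Stage 1's
  bottom (level `L−1`) appends a single refinement conv
  (`ch[L−1] → ch[L−1]`) to the level's ordinary encoder output.
* **Decoder, per step `s`:** at level `d`, a learned 2×2 stride-2
  transposed convolution (shared across steps and stages) lifts the level
  below to `ch[d]`; the *forward skip connection* (FSC) concatenates it
  with the same-level encoder output; the level's step conv reduces
  `2·ch[d] → ch[d]`; a shared refinement conv (`ch[d] → ch[d]`) closes the
  level. The up-convolutions and refinement convs are step-independent:
  each extra step adds exactly one identically-shaped conv unit per block,
  so the parameter count is exactly affine in `n_steps`.
* **Heads.** One 1×1 convolution per stage maps `ch[1]` to `n_classes`
  pre-activations.

Every 3×3 conv unit is conv → batch normalization → ReLU.

### Parameter accounting

`count_parameters()` counts conv and up-conv kernels, biases, batch-norm
scale/shift pairs and the heads; batch-norm running statistics are buffers,
not parameters. The conv bias that precedes a batch normalization is
mathematically absorbed by the normalization's shift; it is kept in the
count (one bias per output channel, the usual bookkeeping for such units)
but neither applied nor trained. Under this convention the default
architecture has 15.04 M trainable parameters, the `ocs = 0.5` variant
3.76 M, and the one- and three-step ablations 10.33 M and 19.76 M — with
`count(n=3) − count(n=2) = count(n=2) − count(n=1)` exactly:

```{r counts, eval = FALSE}
set.seed(1)
count_parameters(build_plnet(plnet_config()))              # 15,043,586
count_parameters(build_plnet(plnet_config(ocs = 0.5)))     #  3,764,994
count_parameters(build_plnet(plnet_config(n_steps = 1)))   # 10,328,930
count_parameters(build_plnet(plnet_config(n_steps = 3)))   # 19,758,242
```

Several published descriptions of such bidirectional architectures are
ambiguous about the exact placement of the merge convolutions; wherever the
wording admitted more than one wiring we fixed the one whose parameter
count reproduces the sizes quoted for the standard, halved-width, one-step
and three-step configurations, and froze it. The scale factor acts almost
quadratically on the count (`count(0.5)/count(1.0) ≈ 0.25`); the small
linear remainder comes from biases, normalization parameters and the
3-channel input stem.

## Training

`train_epl()` implements the two-phase schedule:

1. **Phase 1** (default the first quarter of `max_epochs`): only stage 1 is
   executed and its soft Dice loss optimized.
2. **Phase 2:** all stages run; the loss is the equal-weight mean of the
   per-stage Dice losses, so it stays in `[0, 1]`; all parameters update,
   including stage 1's.

The soft Dice loss is `1 − (2·Σ p·t + ε) / (Σ p + Σ t + ε)` with
`ε = 1e-6` in numerator and denominator, which makes the empty-vs-empty
case a perfect score and keeps the loss differentiable. Multi-class
training averages the per-class soft Dice over the foreground classes of
the softmax output, mirroring how multi-class reports average foreground
classes only.

Optimization is Adam with first-moment decay 0.9 (the conventional reading
of "momentum 0.9" for Adam), second-moment decay 0.999, and a fixed
learning rate (default `1e-4`, the setting appropriate for dataset-scale
training with batch 16). Early stopping monitors the validation loss (the
training loss when no validation set is given) and halts when no new
minimum has been seen for `patience` epochs (default 20); the returned
model carries the best-monitored weights. An optional `stop_loss` target
ends training once the monitored loss is at or below it — convenient for
desk-scale memorization runs. Everything is driven by the R RNG, so a
fixed seed reproduces the loss history bitwise.

Augmentation (optional, off by default) applies one random geometric
transform per sample: rotation uniform in ±25°, horizontal/vertical shifts
uniform in ±15% of each dimension, and independent 50% flips — bilinear
with reflect padding for the image, nearest-neighbor with background
padding for the mask, the identical transform for both.

### Numerical choices

* Batch normalization: per-channel over (H, W, batch); `ε = 1e-5`; running
  statistics updated with momentum 0.1 in training mode and used verbatim
  in inference mode. A block reused by several passes and stages sees a
  different feature distribution on each use, so running statistics are
  kept **per invocation** (as in recurrent batch normalization) while the
  learned scale and shift stay shared — one running average across all
  uses would systematically mismatch every pass at inference time.
  Statistics are buffers, so this does not affect the parameter count.
* Initialization: Kaiming fan-in normal for all kernels, unit scale / zero
  shift for normalizations, zero biases — fixed by the seed in effect at
  `build_plnet()`.
* Max-pooling ties break toward the first (upper/left) element.
* Binary label maps threshold the fused probability at 0.5; multi-class
  maps take the per-pixel argmax.
* Channel rounding under `ocs` is round-half-up with a floor of one.
* The softmax subtracts the row maximum before exponentiation.
* The network numerics (convolution as im2col + BLAS products, the
  reverse-mode tape, Adam) are implemented in the package and verified
  against central finite differences down to `1e-6` in the test suite,
  including gradient flow through blocks shared by several passes and
  stages.

### Design points that were genuinely open

* **Fusion range.** Fusing *all* stage outputs is the default; a
  `fuse_all_stages = FALSE` flag restricts fusion to all but the deepest
  stage for comparison.
* **Backward feature definition.** The backward slot of encoder level `d`
  carries the previous pass's decoder output from one level above, pooled
  together with the encoder feature (the finest level uses the same-scale
  decoder output directly). This keeps every step conv identically shaped
  across passes and stages — the property that makes block sharing and the
  affine step-count law possible — and is the reading consistent with the
  published parameter budgets.
* **Phase boundary.** No published split between coarse and fine phases
  exists; the default gives phase 1 a quarter of the epoch budget,
  overridable via `phase1_epochs`.
* **Stage-1 exclusives.** Stage 1 owns its bottom refinement conv and its
  prediction head; everything else it touches is reused by stage 2. A
  single-stage build at reduced depth therefore has strictly fewer
  parameters than the full model.

## Synthetic fixtures

`generate_fixtures()` produces three families, each a pure function of
`(seed, spec)`:

* `lesion` — one smooth dark blob (an ellipse whose boundary is perturbed
  by low-order Fourier modes) on a skin-toned background, optional dark
  hair-like polylines, Gaussian noise. Mask: blob interior. Emulates
  dermoscopy structure.
* `nuclei` — 5–40 small bright ellipses, possibly touching, on a dark
  noisy background. Mask: their union.
* `ring` — a bright disk (class 1), a muscle-like annulus strictly
  surrounding it (class 2), and an adjacent crescent-shaped chamber
  (class 3) on a dark background, emulating short-axis cardiac geometry.

The default fixture size is 64² (not 224²) so a complete
train–predict–evaluate loop runs in CPU minutes; `plnet_config()`
automatically drops to a four-level plan below 128 px. The generators
reproduce *geometry and contrast*, not photorealism or the intensity
statistics of real scanners. Tests passing on them demonstrate that the
architecture, gradients, training loop and metrics behave as specified and
that the model has the capacity to fit such structure — they say nothing
about accuracy on clinical data.

The desk-scale configuration used in the test suite — 8 lesion fixtures at
64², `ocs = 0.25`, full-batch Adam at `3e-3`/`1e-2`-class learning rates,
at most 200 epochs — was chosen as the smallest setting where memorizing
the training set (fused Dice ≥ 0.95) is a meaningful end-to-end check of
the whole system on one CPU. The multi-class check trains briefly on 50
ring fixtures and verifies the shape and validity of the per-class report
rather than accuracy.

## Metrics

`metric_suite()` computes accuracy, IoU, Dice, sensitivity and specificity
from one-vs-rest confusion counts; `dice = 2·iou/(1+iou)` holds exactly. A
score with a zero denominator is 1 if the class is absent from both maps
and 0 otherwise. `evaluate_model()` computes metrics per image and averages
(the mode matching mean ± deviation reporting; pooled counts are available
via `pooled = TRUE`), reports each foreground class plus their unweighted
average, and adds sample standard deviations across repeated training runs
when several models are supplied.

## Known limitations

* 2D only; no volumetric variant.
* Pure-R numerics: practical for desk-scale experiments and small studies,
  roughly two orders of magnitude slower than GPU frameworks at the
  224² scale of dataset-level training.
* No learning-rate schedules, mixed precision or test-time augmentation.
* Batch-norm statistics from very small batches are noisy; prediction
  quality early in training reflects that.
* The checkpoint format (RDS + YAML sidecar) is R-specific.
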