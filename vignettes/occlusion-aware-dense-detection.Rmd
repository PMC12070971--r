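---
title: "Occlusion-aware dense detection: models, losses, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occlusion-aware dense detection: models, losses, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sddetect)
```

## The problem

Intensive livestock systems pack many near-identical animals into a small
area. Images from such pens show heavy mutual occlusion, truncated bodies at
the frame border, motion blur and uneven illumination. Standard one-stage
detectors degrade here for two compounding reasons: bounding-box regression
is pulled toward neighbouring ground truths, and non-maximum suppression
cannot distinguish a duplicate from a genuinely overlapping neighbour.

`sddetect` re-implements, in R, a single-class dense-detection pipeline built
around four ideas:

1. **Quantifying occlusion.** For a box $B_i$ among boxes $B_j$, the Overlap
   Ratio is
   $$\mathrm{OR}(B_i) = \frac{\mathrm{Area}\big(\bigcup_{j \ne i} (B_i \cap B_j)\big)}{\mathrm{Area}(B_i)},$$
   the fraction of $B_i$ covered by the *union* of its intersections (never
   double counting). An image's OR is the mean over its boxes; a dataset's
   dense stratum keeps images with OR $> 0.5$ **and** more than 40 objects,
   both strict.
2. **An occlusion-aware loss.**
   $L = L_{\mathrm{CIoU}} + \alpha\,L_{\mathrm{RepGT}} + \beta\,L_{\mathrm{RepBox}}$
   with $\alpha = 0.4,\ \beta = 0.6$. CIoU attracts a prediction to its own
   ground truth; RepGT pushes it away from the most-overlapping *foreign*
   ground truth via IoG under a smoothed-log penalty
   ($-\ln(1-x)$ below $\sigma$, linearized above, $C^1$ at the joint);
   RepBox separates predictions assigned to different objects via their
   pairwise IoU.
3. **Wavelet-enhanced downsampling.** Each stride-2 stage transition applies
   a 1×1 stride-2 convolution, then enriches the result with depthwise
   convolutions performed in the orthonormal Haar domain (LL/LH/HL/HH bands,
   recursively on LL), inverse-transformed and added back. Orthonormal
   $\pm 1/2$ filters make analysis an isometry, synthesis its exact inverse
   and adjoint — so backpropagation through the transform is the transform
   itself.
4. **Attention fusion and a shared head.** Stride-4 detail features are
   fused into the stride-8 branch as
   $F_\mathrm{out} = F_\mathrm{low}\odot F_\mathrm{pixel} +
   \mathrm{Conv}_{1\times1}(F_\mathrm{high})\odot(1-F_\mathrm{pixel})$,
   a per-position convex combination steered by a sigmoid gate computed from
   position- and channel-attended streams. The detection head reduces each
   pyramid level to a common middle channel (default 128) with level-specific
   1×1 convolutions, then shares two 3×3 group-normalized blocks and the
   classification/regression branches across levels, with one learnable
   scalar per level on the regression output.

## What is implemented where

| Concern | Entry points |
|---|---|
| Box algebra, OR, dense stratification | `iou`, `iog`, `overlap_ratio`, `image_or`, `dense_subset` |
| Losses with analytic gradients | `ciou_loss`, `smooth_ln`, `repgt_loss`, `repbox_loss`, `occlusion_loss`, `classification_loss` |
| Haar transforms and blocks | `haar_dwt2`, `haar_iwt2`, `wtconv`, `new_weconv` |
| Attention fusion | `new_position_attention`, `new_channel_attention`, `new_pixel_attention`, `opam_fuse` |
| Shared head | `new_gnconv`, `new_ls_head`, `count_head_params` |
| Detector assembly & training | `build_model`, `train_loop`, `assign_targets`, `decode_and_nms`, `count_params`, `estimate_flops` |
| Evaluation | `match_detections`, `average_precision`, `ap_range`, `evaluate_detections` |
| Synthetic scenes | `scene_spec`, `generate_scene`, `generate_dataset` |
| Configuration & CLI | `load_config`, `split_dataset`, `sdd_cli` |

There is no deep-learning framework in this stack, so the package carries its
own CPU engine: conv2d via `im2col` + BLAS, depthwise convolutions, group
normalization, SiLU, max-pooling and nearest upsampling, each with a
hand-written backward pass. The test suite validates every gradient against
central finite differences, end to end through the assembled detector.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `loss$alpha`, `loss$beta` | 0.4, 0.6 | repulsion weights |
| `loss$sigma_repgt/repbox` | 0.5 | smooth-ln switch point; midpoint of its valid range `[0,1)` (source recipe is silent) |
| `loss$epsilon` | 1e-7 | RepBox denominator guard ("a very small constant") |
| `train$lr` / decay | 2e-3, linear to 1% | AdamW, 3 warm-up epochs, weight decay 5e-4, batch 16 |
| `model$weconv$levels/kernel` | 1 / 5 | wavelet depth and depthwise kernel (source silent; one level suffices at toy resolutions) |
| `model$opam$reduction` | 16 | squeeze-excitation bottleneck |
| `model$head$middle_channel` | 128 | shared-head width, the published accuracy/efficiency compromise |
| `model$head$reg_max`, `use_dfl` | 16, on | distribution-focal regression bins; disabling reproduces the plain CIoU+repulsion loss exactly |
| `eval$conf_thr`, `eval$nms_iou` | 0.001, 0.65 | evaluation decoding; 0.65 matches the published visualization protocol |

Variants n/s/m use depth/width multipliers (0.33, 0.25), (0.33, 0.50),
(0.67, 0.75) over base channels 64–1024 (capped at 768 for m). With the
default head, the s-variant lands between 9 and 11.5 M parameters,
bracketing the published baseline-vs-modified pair.

## The synthetic-scene generator

Real crowded-pen imagery is unavailable to a test suite, so the generator
emulates its statistics: 10–80 convex bodies (ellipses with shading, or
speckled blobs) per image, amodal boxes clipped at the frame, a configurable
fraction of edge-truncated instances, low-frequency background texture
(which exercises the wavelet path), Gaussian motion blur, and global
illumination gain drawn from an interval. Placement is rejection-and-relax:
cluster spread starts wide and shrinks until the achieved image OR lands
within ±0.05 of the target, best effort with a warning otherwise. A fixed
seed makes scenes byte-identical.

What a green test on synthetic scenes does **not** establish: transfer to
real animals (no feathers, no lighting physics, no camera noise), NMS
behaviour at real aspect-ratio statistics, or the absolute AP values printed
for the reference datasets — those require the external corpora and
GPU-scale training and are explicitly out of scope. What it does establish:
the geometry, losses, transforms, assignment, decoding and evaluation are
internally consistent and the full pipeline can drive its loss down and
recover its own training annotations.

## Numerical and design choices

* **Feature-map layout** is `(H, W, C)` (native R image layout) rather than
  channel-first; each channel is a contiguous block column-major.
* **Group normalization everywhere.** The original backbone uses batch norm;
  batch statistics are meaningless at CPU toy batch sizes, and GN has the
  same affine parameter count, preserving parameter-table arithmetic. The
  head's GN (16 groups) is the published design.
* **Union computation** for OR uses an exact coordinate-compression sweep;
  the rasterized counting version survives as the test oracle.
* **Repulsion specifics.** `|P+|` divides by *all* positives (those without
  a repulsion ground truth contribute zero). RepBox pairs are unordered and
  counted once; groups are assigned-ground-truth identity. During training,
  overlap fractions are clamped to $1-10^{-9}$ so duplicate boxes cannot
  produce infinite penalties; the exported functions keep the strict domain
  errors.
* **CIoU gradient** differentiates the full expression including the
  $\omega = v/((1-\mathrm{IoU})+v)$ coupling; the identical-box limit
  $(u+v)\to 0$ returns a zero aspect term.
* **Assignment** is task-aligned top-k (k = 10, alignment
  $s^{0.5}\,\mathrm{IoU}^6$) over anchor points inside each ground truth,
  recomputed from decoded boxes each step; the repulsion ground truth is the
  non-assigned one with maximal IoU with the prediction (none if zero).
* **Fusion operator** in the wavelet block and the attention module is
  element-wise addition (the source figure is ambiguous between addition and
  concatenation); the attention streams are reconciled by a stride-2
  convolution on the low branch, a bare linear 1×1 on the high branch.
* **AP** uses COCO 101-point interpolation, labelled in every report, with
  greedy score-order matching and at most one match per ground truth.
* **Odd spatial sizes** reflect-pad before Haar analysis and crop after
  synthesis; adjoints fold the padded row/column gradients back, so
  gradients stay exact at any size.
* **Empty-image OR** is 0 by convention (the statistic is undefined at
  $n = 0$, and 0 keeps dataset means well defined).

## Known limitations

* Single-class only; the multi-class decoupled head exists as a correctness
  stub for ablations, not a tuned alternative.
* Mosaic augmentation (and its disable-late-epochs rule) is out of scope;
  the training loop is plain full-image.
* CPU-only and deliberately small: the engine favours correctness and
  testability over throughput. Toy-scale training (tens of thousands of
  parameters, 64–128 px inputs) runs in minutes; reproducing published
  absolute APs does not fit this artifact.
* The exact neck topology and the GhostNet-style split of the original are
  not specified textually in the source; a PAN-style two-path neck and a
  single fused wavelet path are used and documented here.
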