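---
title: "Crop-row segmentation and navigation-line extraction: methods"
author: "cropnav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crop-row segmentation and navigation-line extraction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Machine-vision guidance of field machinery (weeders, sprayers) in row crops
needs the image-plane centerlines of the crop rows ahead of the vehicle. Two
stages are involved: a per-pixel classification of the scene into *crop row*
vs *background* (soil, stones, shadows — and weeds, which are deliberately
background), and a geometric stage that turns the binary mask into a small
number of straight navigation lines, one per row, robust to missing
seedlings, weed clutter and ragged canopy boundaries.

`cropnav` implements both stages, a seeded synthetic scene generator that
stands in for field imagery, a combined focal + dice training loss, a
confusion-matrix metric suite, and navigation-line error measures.

## The segmentation network

The network is an encoder–decoder in the DeepLabV3+ mould, assembled from
four elements that can be toggled independently (`net_config(variant =)`,
rungs `"A"`, `"A+B"`, `"A+B+C"`, `"A+B+C+D"`):

* **A — lightweight backbone.** A MobileNetV2-style stack of inverted
  residual bottlenecks (1×1 expansion → 3×3 depthwise → 1×1 projection, skip
  at matching dims). Stage layout (expansion t, channels c, repeats n,
  stride s): (1,16,1,1), (6,24,2,2), (6,32,3,2), (6,64,4,2), (6,96,3,1),
  (6,160,3,2), (6,320,1,1), preceded by a stride-2 stem and followed by a
  1×1 convolution to 1280 channels. Stride-2 stages past output stride 16
  run at stride 1 with doubled dilation, so the deep tap stays at output
  stride 16; the shallow tap is taken after the second bottleneck stage
  (output stride 4), the standard low-level feature choice for this decoder
  wiring.
* **B — split-attention bottlenecks.** Each bottleneck's depthwise 3×3 is
  replaced by a split-attention convolution: `radix` parallel depthwise 3×3
  splits; their sum is globally average-pooled into a channel descriptor;
  a bottleneck MLP (reduction 4, minimum width 8) produces per-channel
  logits for every split; a softmax across the radix axis yields weights
  that sum to one per channel; the output is the weighted sum of splits.
  Defaults radix 2, cardinality 1 follow the split-attention literature —
  the block internals are exposed in `sac_spec()` because no single
  canonical choice exists at this size.
* **C — dense atrous pyramid + strip pooling.** Five 3×3 branches with
  dilations 3, 6, 12, 18, 24; branch *l* consumes the concatenation of the
  (1×1-projected) input and all previous branch outputs, passes a 1×1
  bottleneck (128 channels) and emits 64 "growth" channels. Horizontal and
  vertical strip pooling (mean over a full row/column, 1×1 conv, broadcast
  back) contribute two more 64-channel maps that capture the long, thin
  band structure of crop rows; a final 1×1 fuses everything to 256
  channels. When C is off, a plain parallel pyramid (1×1 + dilations
  6/12/18 + image pooling) stands in its place.
* **D — CBAM decoder attention.** On the concatenation of projected shallow
  features (48 ch) and the 4×-upsampled head output: channel attention
  `sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))` (shared MLP, reduction 16),
  then spatial attention `sigmoid(conv7x7([mean_c; max_c]))`, both
  multiplicative. Two 3×3 convolutions and a 1×1 classifier follow, then
  4× bilinear upsampling back to the input size.

Every convolution is followed by batch normalization and ReLU6 except the
attention-logit layers (bare convolutions) and the classifier — the
MobileNetV2 convention. With all four elements on and 2 classes the model
has ≈ 8.09 M trainable parameters, and the count increases strictly along
A < A+B < A+B+C < A+B+C+D (`count_parameters()` sums trainable tensors
only; batch-norm running statistics are buffers).

```{r}
library(cropnav)
model <- build_model(net_config())          # full A+B+C+D
count_parameters(model) / 1e6               # ~8.09
```

### The numerical engine

No deep-learning framework is assumed: the package carries a small
define-by-run reverse-mode autodiff over `(H, W, C, N)` arrays, with C++
kernels (im2col + BLAS for grouped/dilated convolution, a direct loop for
depthwise, bilinear resize with its adjoint) and R-level ops for batch norm,
activations, pooling, strip pooling, concatenation and the attention
algebra. Every op is finite-difference checked in the test suite; the
convolution kernels are additionally checked against a direct-summation
oracle. Training uses Adam (β₁ = 0.9 — the "momentum factor" reading, since
Adam has no classical momentum — β₂ = 0.999) with *decoupled* weight decay
5·10⁻⁴ and cosine annealing of the learning rate from 10⁻³ to 10⁻⁵ over the
epoch budget. A linear batch-size scaling hook for the initial rate exists
(`scale_lr_by_batch`) but is off by default, because the exact coupling rule
between batch size and rate is a free choice.

## Loss and metrics

Training minimizes the unweighted sum of two terms on the softmax
foreground probabilities:

* focal: mean over pixels of −α_t (1 − p_t)^γ log p_t, with p_t the
  probability of the pixel's true class, α_t = α for foreground and 1 − α
  for background. Defaults γ = 2, α = 0.25 — standard focal-loss practice,
  exposed in `loss_config()` since no numeric values are canonical here.
* dice: 1 − (2|A∩B| + ε)/(|A| + |B| + ε) with A the *soft* foreground
  probabilities during training (differentiability) and the hard argmax
  mask in evaluation; ε = 10⁻⁶ guards the empty-mask 0/0.

Evaluation metrics all derive from the binary pixel confusion matrix:
per-class IoU and pixel accuracy averaged over the two classes (the
background class uses TN as its true positives), precision, recall,
f1 = 2TP/(2TP + FP + FN) (identical to the dice coefficient for hard
masks), and overall accuracy (TP + TN)/total — the latter has no stated
formula upstream and is implemented as the natural reading, flagged here.
Degenerate 0/0 ratios are defined as 1 when the class is absent from both
masks and 0 otherwise, with a `degenerate` flag on the result.

## From mask to navigation lines

The geometric stage (`extract_navigation_lines()`) has five steps, each
independently exposed and tested:

1. **Row-instance clustering** (`cluster_rows`). The mask is cut into 20
   equal-height bands; per band, connected components are reduced to their
   centroid x. A 1-D DBSCAN (eps 30 px, min_samples 5) over the pooled
   representative x-coordinates groups them into row instances; noise
   representatives are discarded. DBSCAN runs on band representatives, not
   raw foreground pixels — at min_samples 5 a pixel-level run would be
   trivially satisfied everywhere and could not separate anything. Each
   instance mask is then closed vertically (1×15 kernel) to bridge
   plant-to-plant gaps.
2. **Anchor extraction** (`extract_anchors`). At 10 equidistant heights
   (band centers), the zeroth and first moments of the instance slice give
   the centroid x; empty slices yield no anchor. A compact Canny detector
   (Sobel, non-maximum suppression, 50/150 hysteresis on the 0–255 scale)
   records instance edges as a boundary diagnostic only — centroids come
   from mask moments.
3. **Gap repair** (`repair_anchors`). Missing heights copy the x of the
   nearest detected anchor in |Δy| (up–down search); exact ties resolve
   toward smaller y. Instances with zero detected anchors are dropped with
   a warning.
4. **RANSAC** (`ransac_fit`). K = 100 seeded iterations sample two distinct
   anchors, score the through-line by inliers at perpendicular distance
   < T = 5 px, and keep the best model with at least Min = 10 inliers. The
   best inlier set is refit by *total* least squares — orthogonal
   regression, since the model is a general line ax + by + c = 0 with
   a² + b² = 1 and near-vertical rows are the common case — and the inlier
   set is re-evaluated against the refit line.
5. **Consistency filter** (`consistency_filter`). Inliers are ordered by
   projection along the line; gaps larger than 3× the median inter-anchor
   gap split the sequence, only the longest run is kept (the dominant
   straight segment), and the line is refit if anything was removed. With
   two or fewer inliers there is no meaningful gap statistic and the line
   passes through unchanged.

Instances are ranked by mean x and the central `max_rows_kept` (default 3)
are returned with left/middle/right labels, mirroring the forward guidance
zone of a row-following vehicle. Curved rows are still fit with straight
lines; the consistency filter's longest-run rule is the only concession to
curvature, which matches the intended use (near-field guidance) at reduced
accuracy.

All geometry uses 0-based pixel coordinates, x rightward, y downward,
anchor heights at band centers, and no ground-plane projection — camera
height, tilt and the px-per-cm scale are deliberately out of scope.

Quality is quantified in `angle_deviation()` (acute angle between direction
vectors, arccos(|d₁·d₂|)), `horizontal_deviation()` (mean |x_pred(y) −
x_truth(y)| over sampled heights, x(y) = −(by + c)/a; horizontal lines are
rejected by name), and `anchor_fit_accuracy()` (fraction of anchors within
tol = 5 px, the one pixel threshold the method defines). The deviation
formulas themselves are not prescribed anywhere upstream; the acute-angle
and per-height-offset readings are the natural interpretations of the
reported units (degrees, pixels), and the horizontal deviation is averaged
over the anchor heights rather than taken at a single reference height —
both choices are documented here precisely because they are choices.

## The synthetic scene generator

`generate_scene()` renders quasi-parallel plant rows as chains of lobed,
perturbed ellipses (3–6 cosine lobes, random eccentricity) so that centroid
extraction faces non-circular canopies; plants are omitted independently
with `gap_probability` (missing seedlings, recorded as ground truth); weed
blobs are drawn into the *image only* and never into the mask — inter-row
greenery is background by the labeling semantics; a multiplicative
illumination ramp and soil texture noise complete the scene. Row geometry
is x(y) = x₀ + s·y + curvature·(y − H/2)², with the exact centerline stored
as normalized line coefficients for straight rows and as a sampled polyline
for curved ones.

Defaults encode the documented agronomic geometry of seedling-stage maize —
a 60 cm row spacing and 28 cm plant spacing — as a *ratio*: 120 px and
56 px at a 512 px image width. No px-per-cm scale is defined upstream, so
the generator owns the scale and exposes it. Scenes are bit-reproducible
functions of `seed`; `generate_batch()` uses seed, seed+1, … per element.

What the generator does *not* emulate: perspective foreshortening, real
soil texture, canopy overlap between adjacent plants of different rows,
motion blur, and real weed morphology. Tests passing on synthetic scenes
therefore demonstrate the correctness and robustness of the *geometry* and
the learnability of the *architecture*, not field-grade segmentation
accuracy — the headline field benchmarks are explicitly out of scope here.

## Data preparation

`preprocess()` resizes bilinearly (half-pixel-center convention) to
512×512, scales to [0,1] and standardizes with the ImageNet channel
statistics. `split_dataset()` shuffles with a seed and assigns ⌊r·n⌋
samples to validation and test with the remainder to train, so the three
parts are disjoint and cover everything. `build_augmented_training_set()`
grows *only* the training split to N × 0.8 pairs (default N = 5000) by
repeatedly sampling a source pair and applying one or more transforms:
brightness/contrast (α ∈ [0.8, 1.2], plus an additive term within ±0.1 of
range — the transform is named brightness *and* contrast upstream but
parameterized only by α, so the offset is this package's completion),
horizontal/vertical flips (p = 0.5 each), rotation θ ∈ [−15°, 15°] about
the center with zero border fill (borders are background by the label
semantics; bilinear for images, nearest for masks), 3×3 Gaussian blur, and
Gaussian noise with σ² = 0.01 interpreted on the [0,1] intensity scale (no
scale is stated upstream; [0,1] matches the normalization). Each transform
fires through an independent Bernoulli gate (p = 0.5; only the flip
probabilities are prescribed) and draws are repeated until at least one
fires. Each augmented pair records its source index, so leakage is
auditable. One upstream ambiguity is resolved deliberately: the prose
describes expanding the dataset to 5000 *before* splitting, while the
pipeline pseudocode splits first and augments only the training set to
4000; the two are inconsistent, and this package follows the pseudocode
(split first, no leakage).

## Desk-scale training and problem sizes

`train_model()` runs the seeded loop end to end; a single seed fixes the
split, augmentation draws, weight initialization, shuffling and RANSAC
sampling. The learnability experiment used across the tests runs the full
architecture at reduced width — `desk_net_config()`: width multiplier 0.35,
growth 32, slim decoder — on 20 synthetic 128×128 scenes for 30 epochs at
batch size 8, with 5 held-out scenes for evaluation; these sizes are the
package's chosen desk-scale study conditions, small enough to run on one
CPU core while exercising every structural element of the network. The run
drives training loss well below its first-epoch value and reaches held-out
foreground IoU above 0.5 — a learnability check, not a benchmark claim.

```{r}
scenes <- generate_batch(20, scene_config(image_height = 128L,
                                          image_width = 128L, n_rows = 3L,
                                          row_spacing = 30,
                                          plant_spacing = 14,
                                          plant_radius_range = c(2.5, 4)))
spec <- normalization_spec(resize_to = c(128L, 128L), scale = 1)
pairs <- lapply(scenes, function(s)
  list(image = preprocess(s$image, spec), mask = s$mask))
fit <- train_model(pairs, pairs[1:2], desk_net_config(),
                   train_config(epochs = 30L, batch_size = 8L, seed = 7L))
```

## Numerical choices, degenerate inputs, limitations

* Probabilities are clamped to [10⁻¹², 1] inside logs; batch norm uses
  ε = 10⁻⁵ and momentum 0.1 with biased batch variance for normalization
  and the unbiased estimate in the running statistics.
* Line coefficients are normalized to a² + b² = 1 with a ≥ 0 (b > 0 when
  a = 0), making comparisons sign-stable; the angle measure is additionally
  invariant to sign flips.
* RANSAC resamples duplicate coordinate pairs without consuming the
  iteration's validity; fewer than two anchors is an error, and failing the
  minimum-inlier gate returns `NULL` rather than a bad line.
* An empty mask is a valid input everywhere downstream (empty instance
  list, empty line list), not an error.
* Global max pooling and channel max use first-argmax subgradients, the
  usual convention.
* The timing helper reports mean forward time after a warm-up phase and is
  a hardware-dependent diagnostic, never a test criterion.
* Known limitations: straight-line fits on strongly curved rows; no
  temporal smoothing across frames; no metric (ground-plane) output; the
  engine is CPU-only and desk-scale — full-resolution training on
  thousands of images is out of its intended envelope.
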