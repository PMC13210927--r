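# cropnav

Crop-row perception for agricultural machine guidance, in R: a lightweight
semantic-segmentation network that labels crop-row pixels in RGB field
images, and the geometric post-processing that turns a binary row mask into
per-row navigation lines. The package is aimed at researchers in
agricultural robotics and precision agriculture who need a fully inspectable
desk-scale implementation of this pipeline — every stage is exercisable on
seeded synthetic field scenes, with no dataset or GPU required.

## What it implements

**Segmentation.** An encoder–decoder in the DeepLabV3+ style: a
MobileNetV2-type backbone whose bottleneck depthwise convolutions are
replaced by split-attention convolutions (radix-softmax reweighting of
parallel depthwise splits); a densely connected atrous pyramid (dilations
3/6/12/18/24, each branch consuming all previous branch outputs) fused with
horizontal and vertical strip pooling; and a CBAM-refined decoder
(channel attention `σ(MLP(AvgPool F) + MLP(MaxPool F))`, then spatial
attention `σ(conv₇ₓ₇[mean_c F; max_c F])`). Ablation rungs A, A+B, A+B+C,
A+B+C+D toggle the pieces; the full 2-class model has ≈ 8.09 M trainable
parameters, strictly increasing along the rungs. The network runs on a
small self-contained tensor/autodiff engine with C++ convolution kernels —
no external deep-learning framework.

**Training loss.** `L = L_focal + L_dice` with
`L_focal = −α_t (1−p_t)^γ log p_t` (γ = 2, α = 0.25) and the soft dice loss
`1 − 2|A∩B| / (|A|+|B|)`; Adam (β₁ = 0.9) with decoupled weight decay
5·10⁻⁴ and cosine-annealed learning rate from 10⁻³.

**Evaluation.** Confusion-matrix suite (IoU/mIoU, precision, recall,
mPA, f1 = dice, overall accuracy) and navigation-line error measures
(acute angle deviation in degrees, horizontal distance deviation in px at
sampled heights, anchor fitting accuracy at a 5 px tolerance).

**Navigation lines.** Horizontal-band connected components → 1-D DBSCAN
(eps 30 px, min_samples 5) over representative x-coordinates → per-instance
vertical closing → moment-based anchor centroids at 10 equidistant heights
→ up/down gap repair → RANSAC (K = 100, T = 5 px, Min = 10) with total
least-squares refit → spatial consistency filter → the middle three rows,
labeled left/middle/right.

**Synthetic scenes.** `generate_scene()` renders quasi-parallel rows of
lobed plant canopies (60:28 row-to-plant spacing ratio, 120 px spacing at
512 px width), missing seedlings, weed clutter (image only — never mask
foreground) and illumination gradients, with exact centerline ground truth.

## Worked example

```r
library(cropnav)

scene <- generate_scene(scene_config(n_rows = 5L, seed = 42L))

model <- build_model(net_config())
count_parameters(model) / 1e6
#> parameters: 8.09 M

lines <- extract_navigation_lines(scene$mask, seed = 1)
```

Comparing each fitted line `ax + by + c = 0` against the generator's
ground-truth centerlines prints:

```
left    a= 1.000 b= 0.021 c=  -137.9  inliers=10  angle_dev=0.14 deg  lateral=1.39 px
middle  a= 1.000 b= 0.021 c=  -261.4  inliers=10  angle_dev=0.12 deg  lateral=1.48 px
right   a= 1.000 b= 0.027 c=  -381.4  inliers=10  angle_dev=0.35 deg  lateral=0.82 px
```

All ten anchors per row are RANSAC inliers; the fitted lines sit within a
few tenths of a degree and ~1 px of the true centerlines — the mask is
perfect here, so this isolates the geometric stage's accuracy.
Segmentation metrics come from the same API; flipping 2000 random pixels of
that mask gives:

```
mIoU 0.955  mPA 0.992  precision 0.926  recall 0.992  f1 0.958
```

A 30-epoch desk-scale training run on 20 synthetic 128×128 scenes
(`train_model()` with `desk_net_config()`) drives the combined loss from
1.16 to 0.45 and reaches mean held-out foreground IoU ≈ 0.6 — see the
methods vignette (`vignettes/crop-row-navigation.Rmd`) for the model,
parameter choices and the limits of what synthetic scenes demonstrate.

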