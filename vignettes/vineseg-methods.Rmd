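---
title: "Grape cluster instance segmentation: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grape cluster instance segmentation: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Counting and delineating grape clusters in field photographs is a core
primitive of precision viticulture: yield estimation, harvest robotics and
phenotyping all start from knowing where every cluster is, pixel by pixel.
Clusters are a hard target for plain box detectors — they are irregular,
they overlap, and trunks, wires and leaves routinely cut one physical
cluster into several visible fragments. `vineseg` implements an instance
segmentation detector specialized for this setting, together with the full
data pipeline around it: polygon annotation handling, COCO conversion,
training, prediction and COCO-style evaluation, plus a synthetic scene
generator so that every stage is testable on a CPU with no external data.

## The model

The detector is a two-stage Mask R-CNN style network. A region proposal
network (RPN) scores anchor boxes over a feature pyramid; pooled regions
pass to a classification/box-regression head and, in parallel, to a fully
convolutional mask head that predicts an m×m sigmoid mask per region
(m = 28 by default). RoIAlign — bilinear, quantization-free pooling — maps
each region to the fixed head grids (7×7 for the box head, 14×14 for the
mask head). The training objective is the unweighted sum

L = L_cls + L_box + L_mask,

with cross-entropy classification over {background, grape}, smooth-L1 box
regression on parameterized deltas, and the mask term defined as the mean
per-pixel binary cross-entropy of the target class's mask slice after a
sigmoid. The two standard RPN terms (objectness and anchor regression) are
optimized jointly with the sum, as in the standard two-stage recipe; the
package logs them separately so the three-term breakdown above stays exact.

### The ED backbone

The backbone is a ResNet50 feature pyramid with two modifications, applied
at the points where the pyramid is assembled:

* **Efficient channel attention (ECA)** after each stage output C2–C5. The
  gate pools each channel globally, runs a 1-D convolution of adaptive odd
  width k across the channel axis (no bias, zero padding (k−1)/2), applies
  a sigmoid and rescales the channels. The width follows
  k = |log2(C)/γ + b/γ| rounded to an odd integer with γ = 2, b = 1, so
  k = 3 for 256 channels at C2 up to k = 7 for 2048 at C5. The published
  formula does not pin down the rounding at even or half-integer values;
  we adopt the convention of the original ECA reference implementation —
  floor, then add one if even — and expose an override. ECA adds exactly
  k1+k2+k3+k4 parameters.
* **Dense upsampling convolution (DUC)** in the top-down fusion. Instead of
  nearest-neighbor interpolation, each coarser map is convolved 3×3 to
  C·r² channels and the channels are rearranged into an r× larger grid
  (periodic sub-pixel arrangement, r = 2 between adjacent levels). The
  upsampling is thereby learned, which preserves detail that fixed
  interpolation discards — the property the mask task benefits from.

Stage outputs pass ECA, are reduced to 256 channels by 1×1 convolutions,
fused top-down with DUC and element-wise addition, smoothed with a 3×3
convolution against aliasing artifacts, and P6 is a stride-2 max pool of
P5. The five pyramid levels have strides 4, 8, 16, 32, 64 and a uniform
256-channel width. Anchors use five base sizes {8, 16, 32, 64, 128} input
pixels, one per level, crossed with aspect ratios {0.5, 1, 2} — fifteen
templates in total. Aspect ratio here means height/width: ratio 0.5 gives
an anchor of width s·√2 and height s/√2, preserving area s².

Normalization inside the ResNet blocks uses the frozen-batch-norm form
(per-channel affine), the standard choice when training with batch size 2;
from random initialization it behaves as a learned per-channel scale and
shift.

Because no deep-learning framework is available to R, the package carries
its own minimal layers (conv2d, max-pool, RoIAlign, pixel shuffle, linear)
as C++ kernels with a small reverse-mode tape on top. The test suite
verifies every layer's gradient against central finite differences, DUC
against an independently coded brute-force sub-pixel loop, and RoIAlign
against closed-form bilinear results on affine feature fields.

## Annotation model

Annotations follow the LabelMe convention: polygons with a label and an
optional integer `group_id`. All polygons of one image sharing a group id
are the visible parts of one physical cluster and merge into a single
instance whose box is the tight rectangle over all member vertices — the
"outer box computed from the contours" that replaces manual box
annotation. Conversion to COCO keeps the multi-polygon segmentation (so
split instances remain visibly multi-part), recomputes areas from
rasterized masks, and sets `iscrowd = 0` throughout.

Pixel geometry is fixed package-wide: 0-based continuous coordinates,
pixel (r, c) centered at (c + 0.5, r + 0.5), rasterization by even-odd
fill sampled at pixel centers, boxes in (x, y, w, h). A 10×10 axis-aligned
square at the origin therefore rasterizes to exactly 100 pixels. Group ids
are file-local and collapse on the (label, group id) pair.

The 8:2 train/test split shuffles deterministically per source dataset and
rounds the test count half-up: 218 near-distance images split 174/44. The
published far-distance split (370/94 of 464) is not an exact 8:2; the
splitter follows the rule, not the irregularity.

## The synthetic vineyard generator

Real vineyard imagery for this task is not redistributable, so the
generator emulates the statistical structure the method is built for,
with no claim to photorealism:

* clusters are unions of shaded berry discs scattered around an elliptical
  envelope over a coarse leafy background;
* `scale_regime = "near"` (camera 50–100 cm) gives 1–6 larger clusters per
  image, `"far"` (100–150 cm) 5–16 smaller ones — the two acquisition
  distances the detector must bridge;
* full-height bar occluders (trunks, wires, ropes) are drawn after the
  clusters with probability `occluder_probability` (default 0.3) per
  cluster; every instance's polygons are then re-traced from its visible
  pixels, so occluder-split parts are genuine disjoint polygons sharing a
  group id — exactly how an annotator handles a truncated cluster;
* overlapping clusters keep their full annotated masks (an annotator
  labels each cluster whole); only occluders remove pixels from the ground
  truth, so a scene without occluders contains no group ids by
  construction;
* brightness/contrast/saturation jitter emulates down-light vs back-light
  capture.

Polygons come from an exact pixel-boundary trace (after hole filling, with
4-connected components), so rasterizing a scene's polygons grouped by id
reproduces its ground-truth masks pixel-for-pixel — the property that
anchors the annotation tests. Scenes are bit-reproducible from (config,
seed).

Defaults (cluster counts, berry radii, occluder widths) are free
parameters of the emulation: the source experiments report no cluster
density or occlusion frequency, so values were fixed once at what a
vineyard scene at these distances plausibly shows and are not calibrated
further. What passing tests show is that the pipeline's bookkeeping,
losses, geometry and evaluator are correct and that the model can learn
the task's structure; they cannot certify accuracy on real Chardonnay
images, which differ in texture, lighting continuity and annotation noise.

## Training recipe

The published recipe is the default `train_config()`: SGD with momentum
0.9 (momentum itself is unstated upstream; 0.9 is the standard choice for
this recipe), batch size 2 implemented as true gradient accumulation
before each step, initial learning rate 0.01 decayed ×0.1 every 5000
iterations, weight decay 1e-4, 50 epochs; online augmentation (horizontal
and vertical mirroring, rotation within ±15°, relative crops of 0.8–1.0,
brightness/contrast/saturation jitter — ranges unstated upstream, defaults
logged per run) with all geometry re-derived from transformed polygons;
and multi-scale resize with short edges {640, 672, …, 800} capped at a
long edge of 1443 pixels (the cap is exactly the published sensor's aspect
ratio at short edge 800). The schedule is iteration-based and independent
of epoch bookkeeping.

Two presets exist: `"full"` is the published geometry (bottleneck counts
3/4/6/3, stage widths 256–2048, 256-channel pyramid); `"test"` preserves
the complete ED topology at a quarter of the width with one bottleneck per
stage and a 64-channel pyramid, plus smaller proposal budgets — shape
invariants are re-derived for it in the tests. The learnability check
trains the test preset on four 128×128 synthetic scenes (the `tiny`
preset: ≤3 clusters, occluder probability 0.25) for 300 iterations with
the decay step pulled to iteration 150 and the RPN sampling budget at 128
anchors, and requires the model to recover its own training instances at
mask AP@0.5 ≥ 0.9. Problem sizes throughout
the suite (image sizes, iteration counts, fixture counts) are the
package's own choices for a CPU-scale demonstration.

## Evaluation

The evaluator reproduces the reference COCO protocol: IoU thresholds
0.50:0.05:0.95, greedy best-IoU matching per threshold with each ground
truth used at most once, per-image caps of 1/10/100 detections for AR,
101-point interpolated precision for AP. A prediction counts as a true
positive at IoU ≥ threshold — the reference tooling's convention; the
prose the package follows says "greater than", and we keep ≥ to preserve
oracle equivalence. The report carries both fractions and the 0–100 scale
the field's tables print. The test suite checks the evaluator against an
independent NumPy implementation (`inst/oracle/coco_eval_oracle.py`,
written from the published algorithm, sharing no code with the R path) to
1e-6 on randomized synthetic fixtures for both tasks.

## Numerical and degenerate-input choices

* RoIAlign uses the aligned (half-pixel offset) convention with 2×2
  bilinear samples per output cell; zero-area boxes pool to zeros and are
  flagged with a warning.
* Box deltas clamp log-scale terms at log(1000/16); proposals are clipped
  to the image and sub-10⁻³-pixel boxes discarded.
* Smooth-L1 betas: 1/9 for the RPN, 1 for the box head (configurable).
* Mask targets come from RoIAlign on the instance mask at the mask grid,
  binarized at 0.5; predicted masks are pasted back with bilinear
  interpolation and thresholded at 0.5, so a detection's mask support
  always lies inside its (ceiling-extended) box.
* Inputs with sides not divisible by 64 are zero-padded right/bottom; the
  padding is recorded for coordinate un-mapping.
* Ties in score sorting are resolved stably everywhere so that results
  are platform-independent.
* Training aborts with the offending term named if any loss goes
  non-finite.

## Known limitations

* The full-size model trains far too slowly on a CPU to reproduce the
  published field-data AP numbers; those require the original (unreleased)
  imagery and GPU-scale training. The package demonstrates correctness and
  learnability, not field accuracy.
* The generator's berry-disc clusters lack real texture; transfer of a
  model trained on them to photographs is not expected and not claimed.
* `import_partial_weights()` is a name-intersection convenience hook for
  converted pretrained weights; training from scratch is the tested path.
* Single category only; crowd regions and multi-class scenes are out of
  scope.
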