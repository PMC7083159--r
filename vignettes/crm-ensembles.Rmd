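---
title: "Class-selective relevance mapping and ensemble localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-selective relevance mapping and ensemble localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmens)
```

## The problem

A convolutional network that triages chest radiographs into *normal* and
*abnormal* gives a probability, not an explanation. For clinical review one
wants to know *where* in the image the evidence lies, and whether several
independently trained networks agree on it. `crmens` provides the pieces of
that workflow: a removal-based saliency score for individual networks, a
fusion rule that combines the saliency maps of several networks, a
detection-style evaluation of the resulting heatmaps against annotated
boxes, and the usual prediction-level ensembling and metric machinery
around it.

## The relevance score

Let $f_k(l,m)$ be the activations of the deepest convolutional layer of a
trained classifier ($u \times v$ spatial positions, $K$ channels) and
$S_c$ the score at output node $c = 1,\dots,N$. Removing the spatial
element $(l,m)$ — zeroing all $K$ channels at that position — changes each
output score to $S_c(l,m)$. The class-selective relevance map is

$$R(l,m) \;=\; \sum_{c=1}^{N}\bigl(S_c - S_c(l,m)\bigr)^2 .$$

A position earns a large score if its removal perturbs the output layer
strongly — whether by lowering the winning class score or by raising a
competing one — so the map highlights class-discriminative evidence, not
merely high activation. The sum runs over *all* output nodes and is a
plain sum of squares (no $1/N$): the written definition is implemented
literally.

`crm_bruteforce()` evaluates this definition by actually performing the
$u \cdot v$ removals. Two score conventions are supported:

* **logits** (default): scores taken before the softmax. For networks
  whose head is global average pooling (GAP) followed by a dense layer —
  the heads built by this package — each logit is linear in every spatial
  element, the removal difference has a closed form, and the map is exact:
  $R(l,m) = \sum_c \bigl(\tfrac1Z \sum_k W_{kc} f_k(l,m)\bigr)^2$ with
  $Z = uv$. `crm_closed_form()` computes this directly and agrees with
  brute force to floating-point accuracy (this equivalence is a standing
  oracle test).
* **probabilities**: the same removals measured after the softmax, for
  fidelity experiments where the post-softmax reading is wanted. This path
  always uses brute force.

The choice matters because the score definition leaves either reading
open; the logit default is the one under which the GAP-head algebra is
exact. Maps are kept on their raw score scale; normalization belongs to
the fusion step.

## Fusing maps from several models

Different architectures produce maps at different grid sizes and on
different score scales. `ensemble_crm()` applies, in order:

1. bilinear upscaling of each map to the input-image size;
2. per-map division by its own maximum (`normalize_scale`, default on) so
   that no model dominates by scale alone — raw-scale averaging remains
   available for fidelity;
3. per-map thresholding at 10% of its own maximum, discarding the noisy
   low-score floor;
4. elementwise simple averaging — a pixel's mean is always over *all*
   maps, zero maps included;
5. a display threshold, again at 10% of the ensemble's maximum.

The upscaling uses align-corners bilinear interpolation: interpolated
values are convex combinations of the original scores, so non-negativity
is preserved and original sample values reappear exactly at matching grid
points. The per-map threshold and the final display threshold are both
kept, since the procedure states both. The result compensates for regions
any single model misses while suppressing one-model noise.

## From heatmaps to detections, and scoring them

`extract_boxes()` turns a display-thresholded map into detections: the
8-connected components of nonzero pixels become tight half-open boxes,
components smaller than `min_area` pixels are dropped, and each detection
is scored with *the highest map value inside the box times the model's
abnormal-class probability*. Connected components with a configurable
minimum area are the simplest reproducible box-proposal rule; nothing in
the saliency definition prescribes one.

Boxes are 0-based and half-open, so an RSNA-style `(x, y, width, height)`
record converts exactly as `x_min = x`, `x_max = x + width`. Evaluation
follows detection-benchmark practice:

* `match_detections()`: per image, detections in descending confidence
  greedily claim their best-IoU unmatched ground-truth box; a claim
  succeeds if IoU reaches the threshold, and each ground-truth box
  validates at most one detection.
* `pr_curve()` sweeps the confidence threshold over all distinct
  confidences; `average_precision()` integrates precision over recall with
  the all-point rule $\sum_i (r_i - r_{i-1})\,p_i$, $r_0 = 0$ (no 11-point
  interpolation).
* `mean_average_precision()` averages AP over 10 evenly spaced IoU
  thresholds from 0.10 to 0.60 inclusive — a range that avoids the
  degenerate extremes of very loose and very strict matching. The spacing
  within the range is a package choice; only the endpoints and count are
  given by the procedure it follows.
* `mean_image_iou()` pairs ground-truth boxes and detections greedily by
  descending IoU within each image (each used once; unpaired ground truth
  scores 0), averages per image over ground-truth boxes, then over images.
  This is one defensible reading of "averaging IoU over all annotated
  abnormal images"; best-match-per-image and union-of-boxes readings
  exist, and the function documents which one is implemented.

## Prediction-level ensembles

`majority_vote()`, `simple_average()`, `weighted_average()` and the
stacking pair `fit_stacking()` / `predict()` combine per-model class
probability tables. Votes are cast at threshold 0.5; even-count ties
resolve to *abnormal*, the conservative triage choice (with seven models a
tie cannot occur). Weighted averaging takes any non-negative weights
summing to one — e.g. `c(0.25, 0.25, 0.1, 0.1, 0.1, 0.1, 0.1)` to favour
two strongest base models among seven.

The stacking meta-learner concatenates each model's two class
probabilities into one input vector (seven models give 14 inputs), applies
one hidden layer of 14 rectifier units and a softmax output, and is
trained by full-batch cross-entropy descent (Adam-free, momentum form)
with early stopping on an internal held-out split. Hidden width 14 mirrors
the input width; the hidden activation, optimizer and epoch budget are
open choices documented here rather than prescribed. Training is
deterministic given `seed`. To avoid leakage the meta-learner should be
fit on validation-split predictions; fitting it on the same set used to
report test metrics reproduces the literal two-stage protocol and is the
caller's decision, since the function sees only the tables it is given.

## Metrics and intervals

`metric_suite()` reports accuracy, AUC (trapezoidal, over unique score
cutoffs), sensitivity, specificity, F measure and MCC, with the usual
degenerate-cell conventions (empty-class rates are `NA`; a zero MCC
denominator gives 0). `wilson_interval()` implements the Wilson score
interval; `evaluate_classifier()` applies it to the AUC at per-interval
coverage $\sqrt{0.95}$, so that two simultaneous two-sided statements
carry family coverage 0.95. Treating an AUC as a binomial proportion with
$n$ the test-set size is a pragmatic convention inherited from the
procedure this package follows, and is documented as such — it is not a
DeLong interval.

## Preprocessing

`mask_to_bbox()` takes the tight box over all nonzero lung-mask pixels
(both lungs in one box), `crop_and_resize()` rescales the crop to a fixed
256×256 (aspect deliberately not preserved — the fixed-size rescale is the
stated contract), and `condition()` applies a 3×3 median filter
(reflect-padded borders), a min–max rescale to $[0,1]$ (a constant image
maps to zeros), and optionally standardization by *dataset-level* mean and
standard deviation fitted on a training split with `fit_norm_stats()` and
persisted as JSON. Dataset-level rather than per-image statistics keep the
features identically distributed across images; asking for
standardization before fitting statistics is an error rather than a
silent fallback.

## The synthetic test-bed

Real radiograph collections are far too large to train on here, and their
labels are not redistributable, so every end-to-end claim in this package
is exercised on a generator that mimics the *structure* of the weak
supervision setting: `generate_sample()` draws a brighter body field, two
darker elliptical lung fields (their union is the mask), smooth
low-frequency noise, and — for abnormal samples — one or two additive
Gaussian "opacity" blobs centred inside a lung ellipse. The ground-truth
box of a blob is its $\pm 2\sigma$ rectangle (≈95% of its mass), clipped
to the lung-mask bounding box. The image-level label is *abnormal* exactly
when at least one blob is present.

Defaults: 64×64 images, blob peak amplitude (`contrast`) 0.6, blob
$\sigma$ uniform in 5–9% of the image side, equal class fractions,
lesions placed without overlap. These were chosen once so that a tiny CNN
can learn the task in minutes on one CPU while the blobs remain spatially
localized; they are the study conditions of the test suite, not tuning
knobs. Per-sample seeds derive from the master seed by one seeded draw,
so datasets are bit-reproducible and different master seeds give disjoint
streams.

What the generator does *not* emulate: anatomy (ribs, mediastinum,
devices), projection physics, inter-reader label noise, multi-site
distribution shift, or opacity textures. Passing tests therefore
demonstrate the correctness and internal consistency of the machinery —
not clinical performance.

## The tiny model factory

`tiny_cnn_spec()` follows the custom-architecture rules: three sections of
`depth` identical blocks (3·depth blocks in total), each block a
depth-wise separable convolution with 5×5 kernels plus ReLU; the kernel
count starts at `ceiling(image_size / sqrt(depth))` and doubles per
section; the head is GAP → dropout 0.5 (training only) → dense softmax.
Two deliberate departures, both documented here:

* pooling is placed once per section rather than after every block, so
  that the deepest conv layer keeps a usable spatial grid (`size/4` after
  two pools; the third section feeds GAP directly). Pooling after each of
  up to 12 blocks would collapse a 64-pixel input below one pixel.
* batch normalization is omitted; the blocks are separable conv + ReLU
  only.

The head is exactly GAP-plus-linear, so every built model satisfies the
closed-form relevance-map contract out of the box, and `crm_for_image()`
uses the exact path automatically. Forward pass, backpropagation and the
Adam optimizer are implemented in plain R matrix arithmetic and verified
against finite-difference gradients in the test suite.

Training choices for the desk-scale demonstrations (`train_demo()`,
`run_desk_study()`): three models differing by initialization seed, 16
initial kernels (an explicit narrow choice — the spec-formula default of
64 kernels for a 64-pixel image is wider than desk-scale training needs),
minibatch size 4, Adam with learning rate 0.01 for the trunk and 10× that
for the zero-initialized dense head, dropout 0.5 on the GAP features, at
most 10 epochs with early stopping (patience 5) on a validation split,
and dataset-level input standardization fitted on the training split. The
zero-initialized head makes the first updates a plain logistic fit on the
random separable-conv features — which are already informative — before
the trunk adapts; this removes most seed-to-seed training variance at
these small sample sizes. A run whose validation accuracy is still below
0.7 after four epochs is treated as a failed initialization basin and
reinitialized once with a seeded restart, inside the same epoch budget —
random restarts being the standard remedy when a small network draws a
bad starting point.

## Problem sizes and determinism

The standing end-to-end study (`run_desk_study()`, also executed by
`scripts/acceptance.R`) simulates 200 images of 64×64 pixels, splits them
60/20/20 by sample id, trains the three tiny models for at most 10 epochs
each, and evaluates individual and top-3 ensemble localization on the
held-out 40 images. These sizes keep a full run in the minutes range on a
single CPU while leaving the qualitative comparison meaningful. All
randomness — dataset, split, initialization, dropout, shuffling — derives
from one master seed, so runs are exactly reproducible; different seeds
give statistically similar but not identical numbers.

## What the desk-scale study does and does not show

The standing study reliably demonstrates the machinery end to end: the
tiny models reach high held-out accuracy, their relevance maps
concentrate on the lesions well enough to score mean IoU far above
chance, and the fused map scores between the weakest and strongest
constituent. It does *not* reproduce the qualitative finding that the
fused map beats every constituent: in these runs the ensemble's mean IoU
typically sits a few hundredths *below* the best single model (the
acceptance script reports this difference as `ensemble_minus_best_iou`).
Three properties of the synthetic conditions explain the difference from
the large-scale setting. First, the synthetic label is recoverable from
global brightness alone, so training puts no pressure on spatial
specificity — models with identical classification accuracy differ
widely in localization quality, and averaging in a weakly localizing
member dilutes the best one. Second, the relevance score is
class-selective rather than lesion-selective: positions carrying
normal-class evidence also earn large scores, adding off-lesion support
that varies by model. Third, after thresholding, the fused support
approximates the union of member supports, which inflates boxes relative
to the tightest member. With many independently trained,
comparably strong models — the regime the fusion rule was designed for —
the first effect disappears; at three desk-scale models it dominates.

## Known limitations

* The closed form applies only to GAP-plus-linear heads; other
  architectures go through brute force, at `u·v` forward passes per map.
* Saliency is undefined here for networks without a spatial deepest conv
  layer.
* `mean_image_iou()` is one of several defensible aggregation rules;
  comparisons against numbers computed under a different pairing rule are
  not apples-to-apples.
* The Wilson interval on an AUC is a reporting convention, not a valid
  binomial interval.
* Heatmap PNGs are 8-bit previews; exact scores live in the CSV/JSON
  sidecars.
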