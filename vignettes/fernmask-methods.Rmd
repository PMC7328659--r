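---
title: "Segmenting herbarium sheets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting herbarium sheets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Digitized herbarium sheets carry far more than the plant: rulers, color
bars, barcodes, stamps, institutional labels, and decades of accumulated
dust. Any analysis that feeds whole sheet photographs to a model risks
learning these collection-specific cues instead of botany. fernmask
implements a complete workflow for separating plant tissue from everything
else: automatic preliminary masks by Otsu thresholding, post-processing of
(possibly hand-edited) masks into clean binary ground truth, a compact
encoder–decoder convolutional network for per-pixel segmentation, and
Sørensen–Dice evaluation with per-family reporting. A seeded synthetic
sheet generator makes the whole pipeline testable end to end without any
image downloads.

## Label conventions

A mask is an `H x W` raster whose only values are 0 and 255. The polarity
is fixed package-wide: **white (255) = plant tissue**, black (0) =
everything else. Masks are always written as lossless 8-bit PNG; a lossy
codec would create intermediate gray values and silently destroy binarity.

## Stage 1 — automatic thresholding

The sheet is converted to grayscale with ITU-R BT.601 luma weights
(`0.299 R + 0.587 G + 0.114 B`, the default conversion dialect of the
common imaging libraries this workflow follows). Otsu's method then picks
the threshold `t` maximizing the between-class variance

$$\sigma_b^2(t) = \omega_0(t)\,\omega_1(t)\,(\mu_0(t) - \mu_1(t))^2$$

over the 256-bin histogram, with class 0 = values `<= t`. This is computed
with cumulative-moment recurrences in one pass; the test suite checks it
against an exhaustive 256-threshold scan. Ties take the lowest maximizing
threshold (deterministic, and the convention of the common library
implementations). Dark pixels — plants are darker than the off-white
mounting paper — become the white foreground mask; the background mask is
its pixelwise complement. Degenerate single-valued images (an empty sheet)
do not abort a batch run: they return a flagged result.

## Stage 2 — post-processing

Hand-edited masks re-enter the pipeline here: brush and shape tools leave
antialiased gray edges, so masks are first re-binarized (`> 127` becomes
255). Despeckling then removes small debris that thresholding mislabeled
as plant. It is realized as a `k x k` **median filter** followed by
re-binarization; on binary input this is exactly a majority vote over the
window, which removes any speck smaller than half the window while
preserving edges — a Gaussian blur would instead erode the frond margins
that make these masks valuable. Borders are handled by symmetric
(edge-repeating) reflection so sheet-edge tissue is not spuriously eroded.

Because plants vary in condition and debris load, no single kernel wins
everywhere. The sweep runs three sizes (default 5, 11, 21: small, medium,
large) and writes **all** candidates; choosing the best one is a human
judgement, deliberately not automated (`--pick` selects by index, default
the middle kernel).

One behavior worth knowing: a majority vote on a branching silhouette
slightly rounds concave corners where pinnules meet the pinna — it can add
pixels up to `k %/% 2` away from existing foreground (an invariant the
tests check). On the synthetic scenes this plateaus the despeckled-mask
Dice around 0.97–0.98 against pristine truth even though every actual
speck is removed; the same rounding is implicit in any neighborhood-blur
cleanup of real masks.

## The synthetic sheet generator

`generate_sheet()` produces a deterministic scene per seed: an off-white
mounting sheet (base RGB (245, 242, 228), Gaussian grain, a radial
yellowing gradient emulating paper aging), one to several procedural
fronds, and the standard non-plant elements — label box with text lines,
pastel color-calibration bar, ruler with ticks, barcode, stamp ring — plus
dust/stain debris. The ground truth is recorded *while the plant is
painted*: element pixels are excluded from it, and debris is painted after
truth capture, so it pollutes the image but never the truth. That debris
is precisely the disparity the despeckle stage exists to remove.

Fronds are recursive branching structures: a curved rachis polyline with
alternating blade-like tapered pinnae and (at `branch_depth >= 2`) stubby
marginal pinnule teeth. The calibration (frozen defaults) reflects three
constraints:

* **Otsu separability** — plant and sheet luma ranges must be disjoint by
  a configurable margin (default 40 gray levels; violating configs error).
  On element-free scenes the auto-mask recovers the truth essentially
  exactly (Dice 1.0 to three decimals across seeds).
* **Despeckle compatibility** — plant limbs are everywhere thicker than
  ~8 px while dark element strokes (barcode bars, ruler ticks, label text,
  stamp ring) stay at or below 2 px, so a 5 × 5 majority vote removes the
  latter and preserves the former.
* **Downsampling stability** — the network trains at 128–256 px on
  center-cropped sheets, a 5× reduction; pinnae are drawn as blades
  (~26 px at the base) rather than hairlines so the resized truth is not
  sub-pixel.

Defaults: 910 × 680 px (a 1/10-scale sheet, aspect preserved so the
square-crop path is exercised), 3 fronds in side-by-side mounting bands,
12 pinna pairs, branch depth 2, 250 debris specks per megapixel, and an
8-family invented taxonomy so per-family reporting is exercised without
implying real specimens. Plant fraction lands in roughly 5–15% of sheet
area (regression-tested against the band [0.02, 0.40]).

What the generator does *not* emulate: photographic vignetting and noise
correlation, translucent or overlapping tissue, handwriting, envelope
fragments, and mercuric-chloride staining chemistry. Tests passing on
these scenes demonstrate that the pipeline machinery is correct and that
the network can learn color-plus-context segmentation; they do not certify
performance on real collection imagery.

## Stage 3 — the segmentation network

The model is a U-Net-style fully convolutional encoder–decoder: a 3 × 3
stem, `encoder_depth` stride-2 3 × 3 stages doubling the channel count, a
mirrored decoder of nearest-neighbor ×2 upsamplings with skip
concatenation at every resolution, and a 1 × 1 head producing a one-channel
score map at input resolution. It is implemented in base R matrix algebra:
feature maps are `(H·W) × C` matrices, convolutions are im2col patch
extraction plus one BLAS multiply, and the backward pass scatter-adds
through the same index maps (gradients are verified against finite
differences in development). Weights are He-initialized from a seeded
stream — two builds from one config are bit-identical. Loading external
pretrained encoder weights is deliberately not part of the workflow; the
architecture and training recipe, not any downloaded weights, are the
reproducible content.

**Data handling.** Rectangular inputs are center-cropped to the shorter
side and resized — bilinearly for images, nearest-neighbor for masks, so
masks stay strictly binary through every geometric operation. The center
anchor is the least biased choice for the crop. Network inputs are
standardized per image and channel (zero mean, unit variance); without
this the bright-sheet-dominated, all-positive inputs condition the loss so
badly that the net collapses to predicting background everywhere.

**Augmentation.** Each training sample is redrawn every epoch through:
horizontal flip (p = 0.5) and, each independently at p = 0.75, rotation up
to 10°, zoom up to 1.1×, perspective warp up to 0.2, and a lighting
adjustment up to 0.2. The geometric transforms are composed into a single
homography applied identically to image (bilinear) and mask (nearest,
re-binarized); the lighting adjustment — multiplicative brightness and
contrast, a documented dialect choice since the operator's internals are
not standardized — touches the image only. "Warp" is realized as random
displacement of the four corners, each coordinate uniform within
`warp_max/2` of a side.

**Optimization.** Adam under the one-cycle policy: cosine warmup from
`lr_max/25` over the first 30% of steps, then cosine annealing to
`lr_max/25000` (the policy's common parameterization; the internals are
package choices). The per-step learning-rate trace is recorded and must
match the schedule function pointwise (tested). Two losses are available:
per-pixel binary cross-entropy on sigmoid scores (default) and soft Dice.
On class-imbalanced scenes (plant ≈ 10% of pixels) the Dice loss converges
substantially faster within a short step budget, which is why the
scaled-down benchmark below uses it; with a longer budget both reach the
same place.

## Stage 4 — evaluation

The Sørensen–Dice coefficient `2|A∩B| / (|A|+|B|)` is computed over
foreground pixel sets, with the both-empty case defined as 1.0 (an empty
prediction of an empty truth is correct). Pixel accuracy — the fraction of
agreeing pixels — is reported alongside: the two coincide only when
classes are balanced, and keeping both makes the distinction visible
rather than implicit. Scoring happens at model resolution: the truth mask
is passed through the identical crop/resize geometry as the prediction, so
each image contributes exactly `size²` pixel predictions. Per-family rows
are unweighted means over images within the verbatim `family` string; the
overall mean is unweighted over images.

## Scaled-down benchmark

The package's reference benchmark — recomputed from scratch by
`scripts/acceptance.R` — trains on 200 synthetic sheets (default
configuration) split 160/40, with a depth-3, base-8-channel network at
128 × 128 for 10 epochs (minibatch 4, i.e. 400 one-cycle steps) under the
full augmentation recipe with Dice loss at `lr_max = 0.01`, then reports
mean validation Dice over the 40 held-out sheets. These problem sizes keep the whole run
in the minutes range on a single CPU while still exercising every stage at
realistic ratios (the data-handling bookkeeping — an 80/20 split of 400
images, 65,536 predictions per 256 × 256 mask, ≈21 M training and ≈5 M
validation pixel labels — is reproduced exactly and separately).

## Known limitations

* The synthetic scenes are linearly separable by color up to edge
  blending; real sheets (yellowed paper, faded tissue, poor lighting) are
  not, and transfer of the trained weights to real imagery is out of scope.
* The network is CPU-oriented and deliberately small; it is an
  implementation of the architecture contract, not a performance-tuned
  replica of a pretrained-encoder model.
* Thin stems near one pixel wide at model resolution remain hard — both
  for the median despeckle (corner rounding) and the network — mirroring
  the failure modes reported for sparse, stem-only specimens in real
  collections.
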