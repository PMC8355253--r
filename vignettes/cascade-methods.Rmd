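---
title: "Coarse-to-fine cascaded segmentation of whole-slide images: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine cascaded segmentation of whole-slide images: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsicascade)
```

## The problem

A digitized microscope slide (whole-slide image, WSI) holds billions of
pixels — cervical Pap-smear slides commonly reach ~90,000 × 40,000 px — while
the diagnostically relevant regions (high-grade squamous intraepithelial
lesions and worse) can be a few thousand pixels in total. Running a dense
semantic-segmentation network over every 512 × 512 tile of such a slide is
wasteful: almost all tiles are background. `wsicascade` implements a
coarse-to-fine cascade that spends full-resolution computation only where a
cheap coarse look found evidence.

## The cascade

A slide is formatted into a tile pyramid $\mathcal T = \{t_{l,i,j}\}$,
$l = 1,\dots,N$, where level $N$ is the full-resolution raster and each
coarser level is the next level average-downsampled by $2^z$ per axis
(defaults $N = 3$, $z = 2$, i.e. 4× per level, 16× from level 3 to level 1).
Every level is cut into non-overlapping $512 \times 512$ tiles by ceiling
division; border tiles are zero-padded and their true extent tracked, and
padded pixels are excluded from every maximum and metric below.

Each level has a segmenter $M_l$ mapping a tile to a per-pixel lesion
probability map $P_{l,i,j}(x,y) \in [0,1]$. Processing starts by scoring
*all* level-1 tiles. A binary attention map is thresholded from the
probabilities:

$$a_{l,i,j} = \mathbf 1\left[\max_{x,y} P_{l,i,j}(x,y) \ge \alpha\right],
\qquad \alpha = 0.5 \text{ by default,}$$

with an *inclusive* comparison at exactly $\alpha$. A tile at level $l$ is
selected for inspection when the attention cell at
$(l-1, \lfloor i 2^{-z}\rfloor, \lfloor j 2^{-z}\rfloor)$ is active, so one
active coarse cell wakes up to $2^{2z}$ finer tiles. Unselected tiles are
never touched again. At level $N$ the selected tiles' probabilities are
thresholded at $\alpha$ and stitched into the slide-level binary mask;
everything outside selected tiles is 0.

Two attention granularities are provided. `per_tile` is the literal rule
above. `per_unit` (the default) refines each tile's attention into a
$2^z \times 2^z$ grid of attention units — 16 per tile for $z = 2$ — each
thresholded over its own sub-region. Because a unit's footprint at the next
level is exactly one tile, unit granularity selects a subset of what tile
granularity selects while producing the identical final mask; the package
tests both properties. Both modes are exposed since the tile-level equations
and the 16-unit implementation describe slightly different selectors and
either may be preferred; unit granularity is the default because it does
less work for the same answer.

### When is skipping lossless?

The cascade equals exhaustive dense level-$N$ inference whenever the models
have the *coarse-covers-fine* property: any region positive at level $l$
produces probability $\ge \alpha$ somewhere inside the corresponding
attention cell at every coarser level. The package ships closed-form
threshold segmenters and a synthetic-slide generator engineered so this
property holds *exactly* (below), which turns cascade-versus-dense
equivalence into a bit-identity test rather than a statistical one. For
learned models the property is approximate, and the cascade trades a
bounded risk of missing faint evidence for a large reduction in tiles
processed — on sparse synthetic slides typically under 10 % of the
full-resolution grid.

## The tile segmenter

The reference architecture is a single-stream FCN-32s on a VGG16 backbone:
a 3×3 first convolution with 100-px padding, five conv blocks with ceil-mode
2×2/2 pooling, a valid 7×7 fc6, 1×1 fc7, a 3-plane score layer, one 32×
stride transposed convolution (kernel 64) and a symmetric center crop back to
the input size. `trace_shapes()` reproduces the layer-size arithmetic; for a
512-px input: Conv1_2 710, pool outputs 355/178/89/45/23, fc6/fc7 17,
upsampled 576 = 512 + 2·32, output 512. The single 32×-stride path is
preferred over multi-stream 8×/16× fusion because fused outputs tend to be
overly fragmented on cytology targets. Where published train- and
inference-time feature sizes for the same 512-px input disagree (23 vs 16
at the fc6 stage), we implement the self-consistent train-column arithmetic;
the inference column cannot be produced by any fixed pad/stride assignment
we are aware of. The score layer keeps three planes (background, lesion,
ignore), with the lesion plane defining $P$; the third plane preserves the
printed output shape while the semantics stay binary.

### The trainable reduced-width variant

Training the full stack is a GPU-scale exercise. For CPU-scale experiments
the package provides a faithful *reduced-width* single-stream 32×-stride
variant (`build_fcn32s()`): one 3×3 pad-1 convolution (3 → `width` channels,
default 8) with ReLU, a stride-32 average-pooling downsampling path, a 1×1
three-plane score convolution, fixed bilinear 32× upsampling, softmax. Two
deliberate choices:

* **Average pooling instead of max pooling.** With average pooling the
  coarse score approximates lesion *coverage* within each 32×32 cell, so the
  bilinearly upsampled 0.5-level set tracks the true lesion boundary to
  sub-cell accuracy. Max pooling would fire a whole cell on a single hot
  pixel and systematically dilate predictions.
* **Fixed bilinear upsampling.** This is the classic initialization of the
  FCN deconvolution filter; keeping it fixed removes 64×64×C parameters that
  a desk-scale dataset cannot constrain.

Training is plain stochastic gradient descent on the per-pixel softmax
cross-entropy with dropout on the pooled features and L2 weight decay,
gradients derived analytically and verified against finite differences in
the test suite. `train_config()` defaults to the classic FCN recipe —
learning rate $10^{-10}$ on a *summed* (unnormalized) loss, dropout 0.5,
weight decay $5 \times 10^{-4}$ — and offers a `normalized` loss mode where
the mean per-pixel loss with a learning rate near 1 converges in a few
hundred seeded steps; the package's own experiments use the normalized mode
so they finish in minutes on one CPU. Training is bit-reproducible given the
configuration seed, and a zero learning rate provably leaves parameters
unchanged.

## The synthetic-slide generator

Real annotated cohorts of gigapixel cytology slides are not redistributable,
so the generator emulates their *structure*: large slides, sparse lesions
(default ceiling 1 % lesion pixels), a train/test split at a 68 %/32 % ratio
(97/46 for 143 slides), and exact pixel-level reference masks. Lesions are
rotated ellipses with semi-axes drawn from 40–80 px (a few thousand to a few
tens of thousands of pixels each, matching the "regions as small as a few
thousand pixels" regime); the default desk-scale slide is 4,096 px per side,
and all cascade logic is size-agnostic.

One design choice does real work: lesion evidence lives in a designated
image channel whose background is exactly zero (texture lives in the other
channels as smoothed uniform noise interpolated from a 64-px lattice).
Averaging over any block that contains at least one lesion pixel therefore
stays strictly positive, and with lesion intensities ≥ 0.85 the signal
survives both 16-fold average downsampling and 8-bit quantization. A
threshold segmenter with a small positive cutoff (default 0.002 < 1/255)
then detects every lesion-bearing block at every level — the exact
coarse-covers-fine property the equivalence tests rely on. Per-slide RNG
substreams are derived as root seed + slide counter so any slide of a
dataset can be regenerated independently.

What the generator does **not** emulate: cytological appearance (nuclei,
overlapping cell clusters, hyperchromatic groups), staining variation, scanner
artifacts, or focus problems. Passing the cascade tests therefore
demonstrates the correctness of the pyramid/attention/assembly machinery and
the trainability of the segmenter on separable targets — not clinical
performance. Pixel values are snapped to the 8-bit grid by default (as
scanned images are), which also makes the PNG tile store bit-lossless.

## Evaluation

Pixel-level counts TP/TN/FP/FN are accumulated as doubles (gigapixel slides
overflow 32-bit integers) over non-padded pixels. Metrics: precision
$TP/(TP+FP)$, recall $TP/(TP+FN)$, F-measure $2TP/(2TP+FP+FN)$, Jaccard
$TP/(TP+FP+FN) = F/(2-F)$, specificity $TN/(TN+FP)$. Degenerate slides need
conventions; in the default `reporting` mode a slide with no reference
positives gets recall `NaN` (excluded from group means) and, when positive
mass is absent entirely, precision/F/Jaccard are recorded as 0 — the
convention used in cohort benchmark tables. A `strict` mode propagates every
0/0 as `NaN` instead, and a flag records when a convention fired.

Group summaries default to *macro* aggregation (mean of per-slide metrics,
NaN-recall excluded) because cohort tables are reported that way; note macro
means do not satisfy the $J = F/(2-F)$ identity. A *micro* mode that pools
counts first is provided for users who want the identity to survive
aggregation.

Methods are compared with Fisher's LSD: one-way ANOVA supplies the pooled
error mean square, each pair gets $SE = \sqrt{MSE(1/n_I + 1/n_J)}$, a
two-sided p from the t distribution on $N - k$ df, and a 95 % CI from the
same quantile. No multiplicity adjustment is applied — that is the defining
property of the LSD procedure — and unbalanced groups are allowed.
Throughput projections use the floor-integer patch-rate arithmetic
(`throughput()`, `project_time()`), e.g. a 1392 × 1040 patch at 0.07 s/patch
is 20,681,142 px/s and a 99,600 × 45,552 slide projects to 219 s.

## Numerical choices and problem sizes

* Downsampling between levels is block averaging with ceiling-sized ragged
  borders (border blocks average over the pixels that exist); it is the
  anti-aliased filter the equivalence guarantees are stated against.
* Ties at $\alpha$ are inclusive ($\ge$) everywhere — attention and mask.
* Tile coordinates are 0-based, row-major, with half-open pixel footprints
  $[i \cdot 512, \min((i{+}1) \cdot 512, H))$.
* $N$ defaults to 3 and all logic is tested for $N \in \{1, 2, 3\}$; a
  per-level $\alpha$ override exists but the default applies one threshold
  everywhere.
* Whether per-level weights are distinct or shared is a user choice; the
  training command trains one model per level on level-appropriate
  downsampled annotations (a coarse pixel is positive when its footprint
  contains any lesion).
* The package's own experiments run at desk scale: cascade/dense
  equivalence on twenty 4,096–8,192-px slides; training on sixteen 512-px
  tiles from five 1,024-px slides with evaluation on three held-out slides
  (mean Jaccard ≥ 0.9 in the shipped configuration). These sizes were chosen
  so the full suite runs on a single CPU in minutes while still exercising
  multi-tile, multi-level geometry, ragged borders and padding.

## Limitations

The generator's separable color model makes segmentation deliberately easy;
it validates machinery, not clinical discrimination. The reduced-width
variant has a 3-px receptive field before pooling and cannot learn texture;
it suffices for coverage-style targets only. The LSD comparisons assume
homoscedastic scores across methods, as the pooled-MSE construction implies.
Vendor WSI formats and color management are out of scope; inputs are plain
PNG/TIFF rasters or the package's directory tile store.
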