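---
title: "Screening H&E slides for TMA punching areas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening H&E slides for TMA punching areas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TMAscreen)
library(EBImage)
```

## The screening problem

Tissue MicroArray (TMA) construction starts from an expert marking, on a
whole hematoxylin–eosin (H&E) slide, the regions from which tissue cores
will be punched. TMAscreen automates the pre-selection step for breast
tissue with tubular carcinoma: a slide is cut into a punching grid of
tiles and each tile is called

* **affected** — carries tubular carcinoma,
* **unaffected** — normal glandular tissue, or
* **non-informative** — fat, tears or empty glass, unusable for punching.

The discrimination rests on two histological facts about this tumor
type. First, tubular carcinoma forms many small tubules of nearly equal
caliber scattered at random, whereas normal lobules aggregate into a few
large agglomerates of very heterogeneous footprint; the *size spread* of
nuclear agglomerates therefore separates the two growth patterns.
Second, a carcinomatous tubule is walled by a *single* layer of
epithelial cells while a normal acinus carries a *double* layer
(epithelial plus myoepithelial); the *wall thickness* separates the two
even when the size spread is ambiguous.

## Pipeline

A slide passes through five stages; the first two run once per slide,
the rest once per tile.

### 1. Stain calibration

Staining intensity varies between labs and between batches. Three
luminance anchors — background glass (B), cytoplasm (C) and nuclei (N)
— are estimated by 1-D k-means (k = 3, deterministic quantile
initialization) and mapped onto a reference profile
(B = 235, C = 175, N = 100 by default) by the unique quadratic
`y = A x² + B x + C` through the three anchor pairs. The quadratic is
applied to all three RGB channels with round-half-up to 8 bits. A
quadratic (rather than affine) transfer lets the mid-tone anchor move
independently of the endpoints, which is what inter-batch eosin
variation requires. Slides whose luminance histogram has fewer than
three distinct levels cannot anchor the fit and are passed through
unchanged, marked as skipped.

The slide is then resampled bilinearly to the reference resolution
`r_ref = 0.46` µm/px, so every later threshold can be stated in
micrometer-denominated constants divided by `r_ref²` (areas) or
multiplied by `1/r_ref` (lengths).

### 2. Tiling

The default punching grid is 8 rows × 9 columns over a
6720 × 4200 px slide (tiles ≈ 746 × 525 px ≈ 343 × 242 µm). Tile
widths use floor division with the last row/column absorbing the
remainder, so the grid partitions the slide exactly.

### 3. Informative filter

A tile whose mean luminance exceeds `1.2 · P_ref` (with the default mean
reference intensity `P_ref = 170`: 204) is mostly glass or fat and is
flagged non-informative immediately. Comparisons against thresholds
built from decimal factors carry a `1e-6` slack because, e.g.,
`1.3 × 170` is not exactly representable in doubles.

### 4. Distribution morphometry

Pixels are clustered by k-means (k = 3) in RGB into white / pink / blue
classes; the blue (nuclei) mask is dilated by a Euclidean disk of radius
`round(1/r_ref)` px to fuse nuclei of one wall into a connected
agglomerate, and hole-filled for area measurement. Each 8-connected
component is summarized by its moment-equivalent ellipse; objects
smaller than `64/r_ref²` px² (a lymphocyte footprint) are discarded so
immune infiltrates do not masquerade as tubules. If the **population**
standard deviation of the ellipse areas falls below `95/r_ref²` px² the
tile's agglomerates are size-homogeneous — the random pattern of tubular
carcinoma — and the tile is called affected. Tiles in which
segmentation finds no usable objects are folded into non-informative
rather than given a tissue verdict.

### 5. Local thickness

Size-heterogeneous tiles may still be carcinoma (large, sparse
tubules), so the wall thickness decides. We use the model-independent
local thickness: for every foreground pixel `p`,
`τ(p) = 2·max{ d(x) : |p − x| < d(x) }`, the diameter of the largest
inscribed disk containing `p`. It is computed exactly in three steps
(C++ via Rcpp): exact Euclidean distance transform (everything outside
the frame counts as background), reduction to the *distance ridge* (the
set of non-redundant inscribed disks, kept exactly when no other disk
contains them), and painting of τ over each ridge disk in decreasing
radius order. Thickness is evaluated on the *dilated* nuclei mask
(not the hole-filled one — filling a lumen would masquerade as a thick
wall).

The τ map is rendered to 8 bits as
`clamp(round(255 · τ · r_ref / 20 µm))`, i.e. a 20 µm-thick structure
saturates the display. A pixel is *bright* when its rendered value
reaches `1.3 · P_ref` (221), corresponding to a physical thickness of
about 17.3 µm — above a single 8 µm cell layer plus dilation margin,
below a double 16 µm layer plus margin. If the tile carries more than
`530/r_ref²` bright pixels it contains double-layer epithelium and is
called unaffected; otherwise affected.

Note the deliberate gap between the display ceiling (20 µm) and the
bright cutoff (≈17.3 µm): walls between those two values count as
bright without saturating, so the classification does not depend on the
clamp.

## Worked example

```{r example, eval = FALSE}
spec <- sceneSpec(width = 1344, height = 1344, rows = 3, cols = 3,
                  lumenRangeNormal = c(4, 9),
                  lumenRangeSingleLayer = c(5, 20), seed = 5)
sc <- generateScene(spec)
res <- processSlide(sc$image, rIn = 0.46,
                    config = tmaConfig(rows = 3, cols = 3), seed = 1)
table(predicted = res$diagnoses$label, truth = sc$truth$label)
```

## The synthetic generator

Validating a screening pipeline needs tiles with known ground truth.
`generateScene()` draws the three morphologies directly from the
histological model the classifier exploits:

* **normal** — clustered acini (a parent–child point process: a few
  cluster centres, each with 1–4 overlapping acini) with lumens of
  6–18 µm radius and **two** concentric 8 µm cell layers of nuclei,
  yielding large, size-heterogeneous agglomerates;
* **pathological** — tubules with a **single** 8 µm layer, either
  numerous and size-homogeneous (lumen 8 µm ± 2 %, caught by the
  distribution stage) or sparse and size-heterogeneous (lumen
  6–28 µm, caught only by the thickness stage);
* **fat** — near-white background with sparse vacuole outlines.

The default palette matches the reference profile (background 235,
cytoplasm (230, 180, 200), nuclei (90, 90, 160)) and Gaussian pixel
noise of σ = 5 is overlaid. All structure sizes are given in
micrometers and converted through the scene resolution.

The generator is a caricature, and deliberately so: it contains no
stromal texture, no chromatin structure, no staining gradients, no
out-of-focus regions, and its tubule walls are perfect rings. It is
sufficient to exercise every decision path of the classifier with exact
ground truth — which is what it is for — but measured accuracies on it
are upper bounds, not predictions of clinical performance.

## Numerical conventions

* All 8-bit conversions round **half up** (`floor(x + 0.5)`); base
  `round()` rounds half to even and is platform-stable but produces
  surprising anchors (e.g. 0.5 → 0).
* Reported percentages are **truncated** (floor), not rounded:
  302/360 = 83.9 % prints as 83.
* The area spread uses the **population** standard deviation: it
  describes the object set in one tile, not a sample from a larger one.
* Every seeded routine saves and restores the caller's RNG state, so
  results are reproducible regardless of surrounding code, and two runs
  of `processSlide()` with the same seed are byte-identical.

## Problem sizes

The defaults describe a full slide (6720 × 4200 px, 72 tiles); a slide
of that size processes in a few minutes on one core. The test and
acceptance workloads use 1344 × 1344 px scenes under a 3 × 3 grid —
tiles of 448 px, large enough to hold several complete acini at the
reference resolution — so an end-to-end twenty-slide screen completes
in about five minutes. The evaluation harness mirrors a corpus of
20 slides × 72 tiles with 10 % of tiles dropped as discordant between
observers, leaving 1296 scorable tiles, split 650/323/323 into
train/tune/validation.

## Known limitations

* The classifier targets tubular carcinoma; growth patterns that are
  neither tubule-forming nor lobular (e.g. solid sheets) fall outside
  the model and will land in whichever class their area spread mimics.
* Color segmentation assumes H&E; other stains need their own
  reference profile.
* The informative filter is luminance-only: a tile that is half tumor
  and half glass passes the filter and is judged on its tissue half.
* Thresholds (`64`, `95`, `530`, factors 1.2 / 1.3) are
  micrometer-denominated constants tuned for the reference conditions;
  `tmaConfig()` exposes all of them for re-tuning on other material.
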