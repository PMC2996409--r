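# TMAscreen

Semi-automatic pre-selection of punching areas for Tissue MicroArray
(TMA) construction from hematoxylin–eosin (H&E) stained breast-tissue
slides. Each tile of a punching grid is classified as **affected**
(tubular carcinoma), **unaffected** (normal glandular tissue) or
**non-informative** (fat, tears, empty glass), so that a pathologist
reviews a color-coded overview instead of marking every core by hand.

## The science in two sentences

Tubular carcinoma grows as many small tubules of nearly equal caliber
scattered at random, while normal lobules cluster into a few large
agglomerates of very heterogeneous size — so the *size spread* of
nuclear agglomerates separates the two growth patterns. When that is
ambiguous, the wall decides: a carcinomatous tubule is lined by a
*single* epithelial cell layer (≈8 µm), a normal acinus by a *double*
layer (epithelial + myoepithelial, ≈16 µm), which a model-independent
*local thickness* transform (largest inscribed disk diameter) measures
directly on the nuclei mask.

## Pipeline

1. **Stain calibration** — background / cytoplasm / nuclei luminance
   anchors estimated by k-means and mapped onto a reference profile
   (235 / 175 / 100) by the unique quadratic through the three pairs;
   then bilinear rescaling to the reference resolution 0.46 µm/px.
2. **Tiling** — default 8 × 9 punching grid over a 6720 × 4200 px
   slide; the grid partitions the slide exactly.
3. **Informative filter** — tiles brighter than `1.2 · P_ref` (= 204
   for the default mean reference intensity 170) are non-informative.
4. **Distribution morphometry** — k-means color segmentation, Euclidean
   dilation of the nuclei mask, moment-equivalent ellipses per
   8-connected agglomerate, lymphocyte-size filter (`64 / r_ref²` px²);
   population σ of ellipse areas below `95 / r_ref²` px² ⇒ random
   pattern ⇒ **affected**.
5. **Local thickness** — exact Euclidean distance transform, distance
   ridge, inscribed-disk painting (C++); rendered as
   `round(255 · τ · r_ref / 20 µm)`; more than `530 / r_ref²` pixels at
   or above `1.3 · P_ref` ⇒ double-layer epithelium ⇒ **unaffected**,
   otherwise **affected**.

All thresholds are micrometer-denominated constants exposed through
`tmaConfig()`. See the vignette
(`vignettes/tma-screening-methods.Rmd`) for the full methods account.

## Worked example

Generate a small synthetic slide with known ground truth and screen it:

```r
library(TMAscreen)

spec <- sceneSpec(width = 1344, height = 1344, rows = 3, cols = 3,
                  lumenRangeNormal = c(4, 9),
                  lumenRangeSingleLayer = c(5, 20), seed = 5)
sc  <- generateScene(spec)
res <- processSlide(sc$image, rIn = 0.46,
                    config = tmaConfig(rows = 3, cols = 3), seed = 1)
cbind(res$diagnoses[, c("row", "col", "label", "decision_stage")],
      truth = sc$truth$label)
```

```
  row col           label     decision_stage           truth
1   1   1        affected       distribution        affected
2   1   2      unaffected          thickness      unaffected
3   1   3 non_informative informative_filter non_informative
4   2   1        affected       distribution        affected
5   2   2        affected          thickness        affected
6   2   3      unaffected          thickness      unaffected
7   3   1      unaffected          thickness      unaffected
8   3   2 non_informative informative_filter non_informative
9   3   3 non_informative informative_filter non_informative
```

`res$annotated` is the original slide with each tile framed red
(affected), green (unaffected) or gray (non-informative). Evaluation
uses truncated (floor) integer percentages:

```r
percentMetrics(confusionTiles(res$diagnoses$label, sc$truth$label))
```

```
   accuracy sensitivity specificity
        100         100         100
```

## Command line

```sh
Rscript inst/scripts/tma.R analyze slide.png --resolution 0.46 \
    --out annotated.png --report report.json --seed 1
Rscript inst/scripts/tma.R synth --out scenes/ --slides 5 --seed 3
Rscript inst/scripts/tma.R eval --pred pred.json --truth truth.json
```

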