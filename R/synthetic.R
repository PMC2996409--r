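## Synthetic H&E scene generator. Emulates the three tile morphologies the
## classifier discriminates: (a) fat/empty tiles -- near-white with sparse
## vacuole outlines; (b) normal lobular tissue -- lumens ringed by two
## concentric cell layers of nuclei, clustered into large agglomerates of
## heterogeneous footprint (a parent-child, Neyman-Scott-style point
## process); (c) tubular-carcinoma tissue -- small single-layer tubules at
## uniform random positions, either numerous and size-homogeneous (random
## variant, caught by the distribution stage) or sparse and size-
## heterogeneous (single_layer variant, caught only by the thickness
## stage). Every tile carries its planned ground-truth label.

#' Scene specification
#'
#' Geometry, morphology parameters and palette for [generateScene()].
#' Defaults describe a full screening slide: 6720 x 4200 px at 0.46 um/px
#' under an 8 x 9 punching grid, 8 um cells (single-layer tubule wall
#' 8 um, double-layer acinus wall 16 um), background 235 gray, cytoplasm
#' pink (230,180,200), nuclei blue-violet (90,90,160), Gaussian noise
#' sd 5. Structure sizes are given in micrometers and converted through
#' `resolution`, so smaller scenes need proportionally smaller lumen
#' ranges.
#'
#' @param width,height scene dimensions in px.
#' @param rows,cols punching-grid dimensions.
#' @param resolution um/px.
#' @param classPlan optional `rows x cols` character matrix of tile
#'   classes (`normal`, `pathological`, `fat`); sampled from `mix` when
#'   `NULL`.
#' @param mix named class proportions used when `classPlan` is `NULL`.
#' @param pathologyVariant `"random"` (many size-homogeneous tubules),
#'   `"single_layer"` (sparse size-heterogeneous tubules) or `"mixed"`
#'   (each pathological tile picks one of the two at random).
#' @param cellDiameter epithelial cell diameter in um; anchors wall
#'   thicknesses (1 layer = 1 cell, 2 layers = 2 cells).
#' @param lumenRangeNormal lumen radius range (um) of normal acini.
#' @param lumenPathological tubule lumen radius (um) of the random
#'   variant; `lumenJitter` is its relative spread.
#' @param lumenJitter relative radius jitter of random-variant tubules.
#' @param lumenRangeSingleLayer lumen radius range (um) of the
#'   single-layer variant.
#' @param lobulesPerTile agglomerate clusters per normal tile.
#' @param aciniRange acini count range per cluster.
#' @param tubuleDensity tubules per mm^2 in random-variant tiles.
#' @param nLymphocytes small immune-cell nuclei per tissue tile (exercise
#'   the size filter; they must not change the verdict).
#' @param nGaps white inter-lobular gap ellipses per tissue tile.
#' @param palette list with `background`, `cytoplasm`, `nuclei` RGB
#'   triplets (8-bit).
#' @param noiseSd Gaussian pixel noise standard deviation (8-bit scale).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return named list of class `sceneSpec`.
#' @export
sceneSpec <- function(width = 6720, height = 4200, rows = 8, cols = 9,
                      resolution = 0.46, classPlan = NULL,
                      mix = c(normal = 0.4, pathological = 0.4, fat = 0.2),
                      pathologyVariant = c("mixed", "random", "single_layer"),
                      cellDiameter = 8,
                      lumenRangeNormal = c(6, 18),
                      lumenPathological = 8, lumenJitter = 0.02,
                      lumenRangeSingleLayer = c(6, 28),
                      lobulesPerTile = 4, aciniRange = c(1, 4),
                      tubuleDensity = 350, nLymphocytes = 3, nGaps = 3,
                      palette = list(background = c(235, 235, 235),
                                     cytoplasm = c(230, 180, 200),
                                     nuclei = c(90, 90, 160)),
                      noiseSd = 5, seed = 0) {
  pathologyVariant <- match.arg(pathologyVariant)
  if (cellDiameter <= 0 || resolution <= 0)
    tmaError("cellDiameter and resolution must be positive", "tmaBadSpec")
  if (abs(sum(mix) - 1) > 1e-6 || any(mix < 0))
    tmaError("mix proportions must be non-negative and sum to 1", "tmaBadSpec")
  if (!is.null(classPlan)) {
    if (!is.matrix(classPlan) || nrow(classPlan) != rows ||
        ncol(classPlan) != cols)
      tmaError("classPlan must be a rows x cols matrix", "tmaBadSpec")
    if (!all(classPlan %in% c("normal", "pathological", "fat")))
      tmaError("classPlan entries must be normal/pathological/fat", "tmaBadSpec")
  }
  structure(list(width = width, height = height, rows = rows, cols = cols,
                 resolution = resolution, classPlan = classPlan, mix = mix,
                 pathologyVariant = pathologyVariant,
                 cellDiameter = cellDiameter,
                 lumenRangeNormal = lumenRangeNormal,
                 lumenPathological = lumenPathological,
                 lumenJitter = lumenJitter,
                 lumenRangeSingleLayer = lumenRangeSingleLayer,
                 lobulesPerTile = lobulesPerTile, aciniRange = aciniRange,
                 tubuleDensity = tubuleDensity,
                 nLymphocytes = nLymphocytes, nGaps = nGaps,
                 palette = palette, noiseSd = noiseSd, seed = seed),
            class = "sceneSpec")
}

## ---- drawing primitives (8-bit tile canvases, tw x th x 3) ----

drawDisk <- function(arr, cx, cy, r, col) {
  tw <- dim(arr)[1]; th <- dim(arr)[2]
  xs <- max(1, floor(cx - r)):min(tw, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(th, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(arr)
  inside <- outer((xs - cx)^2, (ys - cy)^2, "+") <= r^2
  for (ch in 1:3) {
    sub <- arr[xs, ys, ch]
    sub[inside] <- col[ch]
    arr[xs, ys, ch] <- sub
  }
  arr
}

drawRing <- function(arr, cx, cy, rIn, rOut, col) {
  tw <- dim(arr)[1]; th <- dim(arr)[2]
  xs <- max(1, floor(cx - rOut)):min(tw, ceiling(cx + rOut))
  ys <- max(1, floor(cy - rOut)):min(th, ceiling(cy + rOut))
  if (!length(xs) || !length(ys)) return(arr)
  d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
  inside <- d2 <= rOut^2 & d2 >= rIn^2
  for (ch in 1:3) {
    sub <- arr[xs, ys, ch]
    sub[inside] <- col[ch]
    arr[xs, ys, ch] <- sub
  }
  arr
}

## rejection-sample n points in [m, w-m] x [m, h-m] with pairwise distance
## >= minSep; returns what fits after maxTries
samplePoints <- function(n, w, h, m, minSep, maxTries = 400) {
  pts <- matrix(numeric(0), ncol = 2)
  if (w - 2 * m <= 0 || h - 2 * m <= 0) return(pts)
  tries <- 0
  while (nrow(pts) < n && tries < maxTries) {
    tries <- tries + 1
    p <- c(runif(1, m, w - m), runif(1, m, h - m))
    if (nrow(pts) == 0 ||
        all((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 >= minSep^2))
      pts <- rbind(pts, p)
  }
  pts
}

addLymphocytes <- function(arr, spec) {
  px <- 1 / spec$resolution
  r <- 3 * px                      # 6 um immune-cell nucleus
  pts <- samplePoints(spec$nLymphocytes, dim(arr)[1], dim(arr)[2],
                      m = r + 4, minSep = 8 * r)
  for (i in seq_len(nrow(pts)))
    arr <- drawDisk(arr, pts[i, 1], pts[i, 2], r, spec$palette$nuclei)
  arr
}

addGaps <- function(arr, spec) {
  tw <- dim(arr)[1]; th <- dim(arr)[2]
  r <- 0.06 * min(tw, th)
  pts <- samplePoints(spec$nGaps, tw, th, m = r + 2, minSep = 4 * r)
  for (i in seq_len(nrow(pts)))
    arr <- drawDisk(arr, pts[i, 1], pts[i, 2], r * runif(1, 0.7, 1.3),
                    spec$palette$background)
  arr
}

drawFatTile <- function(tw, th, spec) {
  arr <- array(rep(spec$palette$background, each = tw * th), c(tw, th, 3))
  r <- 0.12 * min(tw, th)
  pts <- samplePoints(4, tw, th, m = r + 2, minSep = 1.5 * r)
  for (i in seq_len(nrow(pts))) {
    ri <- r * runif(1, 0.5, 1.5)
    arr <- drawRing(arr, pts[i, 1], pts[i, 2], ri - 2, ri,
                    spec$palette$cytoplasm)
  }
  arr
}

drawAcinus <- function(arr, cx, cy, rLumen, wall, spec) {
  arr <- drawDisk(arr, cx, cy, rLumen + wall, spec$palette$nuclei)
  drawDisk(arr, cx, cy, rLumen, spec$palette$background)
}

drawNormalTile <- function(tw, th, spec) {
  px <- 1 / spec$resolution
  arr <- array(rep(spec$palette$cytoplasm, each = tw * th), c(tw, th, 3))
  arr <- addGaps(arr, spec)
  wall <- 2 * spec$cellDiameter * px          # two concentric cell layers
  maxOut <- max(spec$lumenRangeNormal) * px + wall
  offMax <- 0.5 * maxOut
  margin <- maxOut + offMax + 8
  minSep <- 2 * (maxOut + offMax) * 0.9
  centers <- samplePoints(max(2, spec$lobulesPerTile), tw, th, margin, minSep)
  for (i in seq_len(nrow(centers))) {
    k <- sample(spec$aciniRange[1]:spec$aciniRange[2], 1)
    lumens <- runif(k, spec$lumenRangeNormal[1], spec$lumenRangeNormal[2]) * px
    ## acinus positions: first at the cluster centre, the rest tightly
    ## overlapping so the cluster forms one merged agglomerate
    for (j in seq_len(k)) {
      if (j == 1) { cx <- centers[i, 1]; cy <- centers[i, 2] }
      else {
        ang <- runif(1, 0, 2 * pi); dd <- runif(1, 0.3, 0.9) * maxOut
        cx <- centers[i, 1] + dd * cos(ang)
        cy <- centers[i, 2] + dd * sin(ang)
      }
      arr <- drawAcinus(arr, cx, cy, lumens[j], wall, spec)
    }
  }
  addLymphocytes(arr, spec)
}

drawPathologicalTile <- function(tw, th, spec, variant) {
  px <- 1 / spec$resolution
  arr <- array(rep(spec$palette$cytoplasm, each = tw * th), c(tw, th, 3))
  arr <- addGaps(arr, spec)
  wall <- spec$cellDiameter * px              # one cell layer
  if (variant == "random") {
    areaMm2 <- (tw * spec$resolution / 1000) * (th * spec$resolution / 1000)
    n <- max(6, roundHalfUp(spec$tubuleDensity * areaMm2))
    rLum <- spec$lumenPathological *
      (1 + runif(n, -spec$lumenJitter, spec$lumenJitter)) * px
  } else {
    n <- max(5, roundHalfUp(spec$lobulesPerTile * 2))
    rLum <- runif(n, spec$lumenRangeSingleLayer[1],
                  spec$lumenRangeSingleLayer[2]) * px
  }
  maxOut <- max(rLum) + wall
  pts <- samplePoints(n, tw, th, m = maxOut + 8, minSep = 2 * maxOut + 16)
  for (i in seq_len(nrow(pts)))
    arr <- drawAcinus(arr, pts[i, 1], pts[i, 2], rLum[i], wall, spec)
  addLymphocytes(arr, spec)
}

drawTile <- function(class, tw, th, spec, variant = NA_character_) {
  switch(class,
         fat = drawFatTile(tw, th, spec),
         normal = drawNormalTile(tw, th, spec),
         pathological = drawPathologicalTile(tw, th, spec, variant),
         tmaError(paste("unknown tile class:", class), "tmaBadSpec"))
}

#' Generate one tile of a given morphology
#'
#' Stand-alone counterpart of [generateScene()] for unit-level work:
#' draws a single tile (noise included) with the palette and morphology
#' parameters of `spec`.
#'
#' @param class `"normal"`, `"pathological"` or `"fat"`.
#' @param width,height tile size in px.
#' @param spec a [sceneSpec()].
#' @param seed integer seed.
#' @param variant pathological variant (`"random"` or `"single_layer"`);
#'   defaults to the spec's resolved variant.
#' @return RGB [EBImage::Image].
#' @export
generateTile <- function(class, width, height, spec = sceneSpec(),
                         seed = spec$seed, variant = NULL) {
  withLocalSeed(seed, {
    if (is.null(variant))
      variant <- if (spec$pathologyVariant == "mixed")
        sample(c("random", "single_layer"), 1) else spec$pathologyVariant
    arr <- drawTile(class, width, height, spec, variant)
    if (spec$noiseSd > 0)
      arr <- arr + rnorm(length(arr), 0, spec$noiseSd)
    image8(roundHalfUp(arr))
  })
}

#' Generate a synthetic H&E scene with per-tile ground truth
#'
#' Draws every tile of the punching grid according to the class plan
#' (sampled from `spec$mix` when absent), then overlays Gaussian pixel
#' noise. Deterministic given the spec (including its seed).
#'
#' @param spec a [sceneSpec()].
#' @return list with `image` (RGB [EBImage::Image]), `truth` (row-major
#'   data.frame: `row`, `col`, `class`, `variant`, `label` where the label
#'   is `unaffected` / `affected` / `non_informative`), and `grid` (the
#'   [TmaGrid-class]).
#' @export
generateScene <- function(spec = sceneSpec()) {
  grid <- makeGrid(spec$width, spec$height, spec$rows, spec$cols)
  tb <- tileBounds(grid)
  withLocalSeed(spec$seed, {
    classes <- if (!is.null(spec$classPlan)) as.vector(t(spec$classPlan))
      else sample(names(spec$mix), nTiles(grid), replace = TRUE,
                  prob = spec$mix)
    variants <- ifelse(classes == "pathological",
                       switch(spec$pathologyVariant,
                              mixed = sample(c("random", "single_layer"),
                                             nTiles(grid), replace = TRUE),
                              rep(spec$pathologyVariant, nTiles(grid))),
                       NA_character_)
    canvas <- array(0, c(spec$width, spec$height, 3))
    for (i in seq_len(nTiles(grid))) {
      b <- tb[i, ]
      tw <- b$x1 - b$x0; th <- b$y1 - b$y0
      canvas[(b$x0 + 1):b$x1, (b$y0 + 1):b$y1, ] <-
        drawTile(classes[i], tw, th, spec, variants[i])
    }
    if (spec$noiseSd > 0)
      canvas <- canvas + rnorm(length(canvas), 0, spec$noiseSd)
    truth <- data.frame(row = tb$row, col = tb$col, class = classes,
                        variant = variants,
                        label = c(normal = "unaffected",
                                  pathological = "affected",
                                  fat = "non_informative")[classes],
                        stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(image = image8(roundHalfUp(canvas)), truth = truth, grid = grid)
  })
}

#' Generate a labelled multi-slide dataset
#'
#' Produces `nSlides` scenes with randomized per-tile class plans and an
#' optional discordant-tile dropout emulating tiles on which two experts
#' disagree: `round(dropout * total)` tiles are flagged `discordant` and
#' excluded from scoring.
#'
#' @param nSlides number of slides.
#' @param spec template [sceneSpec()]; each slide gets its own derived
#'   seed and a plan sampled from `spec$mix`.
#' @param seed master seed.
#' @param dropout fraction of tiles flagged discordant.
#' @param render if `FALSE`, skip pixel rendering (truth and bookkeeping
#'   only; `image` is `NULL`).
#' @return list of `list(image, truth, grid)` per slide; each `truth`
#'   gains a logical `discordant` column. The total number of scorable
#'   (non-discordant) tiles is attached as attribute `scorable`.
#' @export
generateLabeledDataset <- function(nSlides, spec = sceneSpec(), seed = 0,
                                   dropout = 0, render = TRUE) {
  if (dropout < 0 || dropout >= 1)
    tmaError("dropout must lie in [0, 1)", "tmaBadSpec")
  total <- nSlides * spec$rows * spec$cols
  seeds <- withLocalSeed(seed, sample.int(.Machine$integer.max - 1, nSlides))
  drop <- withLocalSeed(seed + 1,
                        sample.int(total, roundHalfUp(dropout * total)))
  slides <- lapply(seq_len(nSlides), function(s) {
    sp <- spec; sp$seed <- seeds[s]; sp$classPlan <- NULL
    out <- if (render) generateScene(sp) else {
      grid <- makeGrid(sp$width, sp$height, sp$rows, sp$cols)
      tb <- tileBounds(grid)
      classes <- withLocalSeed(sp$seed,
        sample(names(sp$mix), nTiles(grid), replace = TRUE, prob = sp$mix))
      list(image = NULL,
           truth = data.frame(row = tb$row, col = tb$col, class = classes,
                              variant = NA_character_,
                              label = c(normal = "unaffected",
                                        pathological = "affected",
                                        fat = "non_informative")[classes],
                              stringsAsFactors = FALSE),
           grid = grid)
    }
    rownames(out$truth) <- NULL
    nt <- nrow(out$truth)
    idx <- (s - 1) * nt + seq_len(nt)
    out$truth$discordant <- idx %in% drop
    out
  })
  attr(slides, "scorable") <- total - length(drop)
  slides
}
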