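## Per-tile decision cascade and per-slide orchestration.
##
## Stage 1 screens out fat / empty tiles by mean luminance; stage 2 calls a
## tile affected when its agglomerate size distribution is random (low area
## spread); stage 3 separates single-layer tubules (affected) from
## double-layer acini (unaffected) by the bright-pixel count of the
## rendered thickness map. Stages short-circuit in that order.

#' Pipeline configuration
#'
#' All tunable thresholds in one flat block, with the screening defaults:
#' `informativeFactor` (multiple of `pRef` above which a tile is
#' non-informative), `sizeConst` (lymphocyte size filter, um^2-scale),
#' `stdConst` (randomness threshold on the area spread), `brightFactor`
#' (multiple of `pRef` defining a bright thickness pixel),
#' `brightCountConst` (bright-pixel count threshold), `tauDisplayMax`
#' (thickness in um rendered as intensity 255), `darkFraction` (fraction
#' of the nuclei cluster retained), `dilationRadius` (px; `NULL` means
#' `round(1/rRef)`), grid dimensions and seed.
#'
#' @param informativeFactor,sizeConst,stdConst,brightFactor,brightCountConst
#'   decision thresholds, see above.
#' @param tauDisplayMax thickness rendering ceiling in um.
#' @param darkFraction fraction of blue-cluster pixels kept as nuclei.
#' @param dilationRadius structuring-element radius in px, or `NULL`.
#' @param rows,cols punching-grid dimensions.
#' @param seed integer seed for the k-means restarts.
#' @return named list of class `tmaConfig`.
#' @export
tmaConfig <- function(informativeFactor = 1.2, sizeConst = 64, stdConst = 95,
                      brightFactor = 1.3, brightCountConst = 530,
                      tauDisplayMax = 20, darkFraction = 1.0,
                      dilationRadius = NULL, rows = 8, cols = 9, seed = 0) {
  cfg <- list(informativeFactor = informativeFactor, sizeConst = sizeConst,
              stdConst = stdConst, brightFactor = brightFactor,
              brightCountConst = brightCountConst,
              tauDisplayMax = tauDisplayMax, darkFraction = darkFraction,
              dilationRadius = dilationRadius, rows = rows, cols = cols,
              seed = seed)
  num <- cfg[!vapply(cfg, is.null, logical(1))]
  if (any(vapply(num, function(x) !is.numeric(x) || x <= 0, logical(1)) &
          names(num) != "seed"))
    tmaError("configuration factors must be positive numbers", "tmaBadConfig")
  structure(cfg, class = "tmaConfig")
}

#' Read / write a configuration as flat JSON
#'
#' @param path file path.
#' @param config a [tmaConfig()] list.
#' @return `readConfig` returns the configuration; `writeConfig` returns
#'   `path` invisibly. Round-trips losslessly.
#' @export
readConfig <- function(path) {
  j <- read_json(path, simplifyVector = TRUE)
  do.call(tmaConfig, j[!vapply(j, is.null, logical(1))])
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  write_json(config[!vapply(config, is.null, logical(1))], path,
             auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Informative-tile filter
#'
#' Tiles brighter than `informativeFactor * pRef` mean luminance contain
#' no tissue or mainly fat and are excluded from diagnosis.
#'
#' @param tile calibrated RGB tile.
#' @param profile a [ReferenceProfile-class].
#' @param informativeFactor brightness threshold as a multiple of `pRef`.
#' @return `"informative"` or `"non_informative"`.
#' @export
informativeFilter <- function(tile, profile = ReferenceProfile(),
                              informativeFactor = 1.2) {
  m <- mean(luminance8(tile))
  if (m > informativeFactor * pRef(profile) + THRESH_EPS) "non_informative"
  else "informative"
}

emptyDiagnosis <- function(row = NA_integer_, col = NA_integer_) {
  data.frame(row = row, col = col, label = NA_character_,
             mean_intensity = NA_real_, n_objects = NA_integer_,
             n_after_filter = NA_integer_, area_std = NA_real_,
             bright_count = NA_integer_, decision_stage = NA_character_,
             note = NA_character_, stringsAsFactors = FALSE)
}

#' Classify one tile
#'
#' Runs the three-stage cascade on a calibrated, resolution-normalized
#' tile and records all intermediate diagnostics. Degenerate tiles (fewer
#' than three distinct colors, so the color segmentation cannot run) are
#' folded into `non_informative` with a note instead of failing a slide
#' run. A tile with no agglomerates left after the size filter has area
#' spread 0 and is therefore called random (affected) at stage 2.
#'
#' @param tile RGB tile.
#' @param profile a [ReferenceProfile-class].
#' @param config a [tmaConfig()] list.
#' @param seed seed for the segmentation restarts.
#' @param row,col optional 1-based tile indices for the report.
#' @return one-row data.frame: `row`, `col`, `label`, `mean_intensity`,
#'   `n_objects`, `n_after_filter`, `area_std`, `bright_count`,
#'   `decision_stage`, `note`. Diagnostics of stages not reached are `NA`.
#' @export
classifyTile <- function(tile, profile = ReferenceProfile(),
                         config = tmaConfig(), seed = config$seed,
                         row = NA_integer_, col = NA_integer_) {
  out <- emptyDiagnosis(as.integer(row), as.integer(col))
  out$mean_intensity <- mean(luminance8(tile))
  r <- rRef(profile)

  if (out$mean_intensity > config$informativeFactor * pRef(profile) + THRESH_EPS) {
    out$label <- "non_informative"; out$decision_stage <- "informative_filter"
    return(out)
  }

  seg <- tryCatch(segmentTile(tile, seed = seed),
                  tmaDegenerateTile = function(e) NULL)
  if (is.null(seg)) {
    out$label <- "non_informative"; out$decision_stage <- "informative_filter"
    out$note <- "degenerate_segmentation"
    return(out)
  }

  nmask <- nucleiMask(tile, seg, darkFraction = config$darkFraction)
  dilated <- cleanMask(nmask, rRef = r, radius = config$dilationRadius,
                       fill = FALSE)
  filled <- EBImage::fillHull(dilated)

  ell <- fitEllipses(filled)
  kept <- filterLymphocyteSized(ell, rRef = r, sizeConst = config$sizeConst)
  out$n_objects <- nrow(ell)
  out$n_after_filter <- nrow(kept)
  out$area_std <- if (nrow(kept) > 0) areaStd(kept) else 0
  if (classifyDistribution(out$area_std, rRef = r,
                           stdConst = config$stdConst) == "random") {
    out$label <- "affected"; out$decision_stage <- "distribution"
    return(out)
  }

  tau <- localThickness(dilated)
  img8 <- renderThickness(tau, rRef = r, tauDisplayMax = config$tauDisplayMax)
  out$bright_count <- countBright(img8, profile,
                                  brightFactor = config$brightFactor)
  layering <- classifyLayering(out$bright_count, rRef = r,
                               brightCountConst = config$brightCountConst)
  out$label <- if (layering == "single_layer") "affected" else "unaffected"
  out$decision_stage <- "thickness"
  out
}

#' Process a whole slide
#'
#' Calibrates the slide to the reference profile, rescales it to the
#' reference resolution, cuts the punching grid, classifies every tile
#' independently (tile `i` uses seed `seed + i`), and reassembles the
#' annotated overview. Deterministic given the seed.
#'
#' @param image RGB [EBImage::Image] or array, or a path readable by
#'   [EBImage::readImage()].
#' @param rIn acquisition resolution of the slide in um/px.
#' @param profile a [ReferenceProfile-class].
#' @param config a [tmaConfig()] list (grid dimensions and thresholds).
#' @param seed base seed.
#' @return list with `diagnoses` (row-major data.frame of per-tile
#'   records), `annotated` (RGB [EBImage::Image] of the slide's
#'   post-rescale dimensions) and `grid` (the [TmaGrid-class]).
#' @export
processSlide <- function(image, rIn, profile = ReferenceProfile(),
                         config = tmaConfig(), seed = config$seed) {
  if (is.character(image)) {
    if (!file.exists(image))
      tmaError(paste("cannot read image:", image), "tmaInputError")
    image <- EBImage::readImage(image)
  }
  img <- calibrateSlide(image, profile)
  img <- rescaleToResolution(img, rIn, profile)
  grid <- makeGrid(dim(img)[1], dim(img)[2], rows = config$rows,
                   cols = config$cols)
  tiles <- cutTiles(img, grid)
  tb <- tileBounds(grid)
  diagnoses <- do.call(rbind, lapply(seq_along(tiles), function(i)
    classifyTile(tiles[[i]], profile, config, seed = seed + i,
                 row = tb$row[i], col = tb$col[i])))
  annotated <- annotateAndReassemble(tiles, diagnoses$label, grid)
  list(diagnoses = diagnoses, annotated = annotated, grid = grid)
}
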