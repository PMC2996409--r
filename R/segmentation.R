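## Three-class k-means color segmentation of a tile in RGB space, followed
## by extraction and morphological clean-up of the nuclei mask. The cluster
## label arbitrariness of k-means is resolved by ranking cluster centers by
## luminance (brightest -> white, middle -> pink, darkest -> blue).

#' Segment a tile into white / pink / blue classes
#'
#' Pixels are clustered with k-means (k = 3, Euclidean distance in RGB,
#' `nstart` random restarts under a fixed seed). On tiles larger than
#' `maxFit` pixels the centers are fitted on a random subsample and every
#' pixel is then assigned to its nearest center, which keeps large tiles
#' tractable without changing the assignment rule.
#'
#' @param tile RGB [EBImage::Image] or array.
#' @param seed integer seed making the restarts reproducible.
#' @param nstart number of k-means restarts.
#' @param maxFit maximum number of pixels used to fit the centers.
#' @return a [SegmentationResult-class].
#' @export
segmentTile <- function(tile, seed = 0, nstart = 5, maxFit = 20000) {
  v <- pixels8(tile)
  if (length(dim(v)) != 3L) stop("tile must be an RGB image")
  w <- dim(v)[1]; h <- dim(v)[2]
  px <- matrix(v, ncol = 3)
  ncolors <- nrow(unique(px))
  if (ncolors < 3)
    tmaError("tile has fewer than 3 distinct colors", "tmaDegenerateTile")
  km <- withLocalSeed(seed, {
    fit <- if (nrow(px) > maxFit) px[sample.int(nrow(px), maxFit), , drop = FALSE]
           else px
    if (nrow(unique(fit)) < 3) fit <- unique(px)
    tryCatch(
      suppressWarnings(kmeans(fit, centers = 3, nstart = nstart,
                              iter.max = 100)),
      error = function(e) tmaError(paste("k-means failed:", conditionMessage(e)),
                                   "tmaDegenerateTile"))
  })
  centers <- km$centers
  ## nearest-center assignment of all pixels
  d2 <- sapply(1:3, function(k)
    (px[, 1] - centers[k, 1])^2 + (px[, 2] - centers[k, 2])^2 +
    (px[, 3] - centers[k, 3])^2)
  cl <- max.col(-d2, ties.method = "first")
  lum <- centers %*% c(0.299, 0.587, 0.114)
  rank <- order(lum, decreasing = TRUE)   # white, pink, blue
  mk <- function(k) matrix(cl == k, nrow = w, ncol = h)
  new("SegmentationResult", white = mk(rank[1]), pink = mk(rank[2]),
      blue = mk(rank[3]))
}

#' Extract the nuclei mask from a segmentation
#'
#' Keeps the darkest `darkFraction` of blue-cluster pixels by luminance
#' (1.0 keeps the whole nuclei cluster) and returns a binary mask.
#'
#' @param tile the segmented RGB tile.
#' @param seg its [SegmentationResult-class].
#' @param darkFraction fraction of blue pixels retained, darkest first.
#' @return binary matrix (0/1) of nuclei pixels.
#' @export
nucleiMask <- function(tile, seg, darkFraction = 1.0) {
  blue <- blueMask(seg)
  if (darkFraction >= 1 || !any(blue)) return(blue * 1)
  lum <- luminance8(tile)
  cutoff <- quantile(lum[blue], darkFraction, names = FALSE, type = 1)
  (blue & lum <= cutoff) * 1
}

## exact Euclidean disk structuring element: offsets with dx^2+dy^2 <= r^2
diskKernel <- function(radius) {
  n <- 2L * radius + 1L
  off <- seq_len(n) - radius - 1L
  k <- outer(off^2, off^2, "+") <= radius^2
  k * 1
}

#' Morphological clean-up of the nuclei mask
#'
#' Dilation by a Euclidean disk (default radius `round(1/rRef)` px, one
#' cell-membrane step of about 1 um) followed by hole filling (background
#' regions not connected to the tile border). Thickness analysis uses
#' `fill = FALSE` so gland lumens stay open; the agglomerate-footprint
#' morphometry uses the filled mask.
#'
#' @param mask binary matrix.
#' @param rRef resolution in um/px, used for the default radius.
#' @param radius dilation radius in px; overrides `rRef` when given.
#' @param fill fill holes after dilation?
#' @return cleaned binary matrix; always a superset of the input.
#' @export
cleanMask <- function(mask, rRef = 0.46, radius = NULL, fill = TRUE) {
  mask <- (unclass(mask) != 0) * 1
  if (is.null(radius)) radius <- roundHalfUp(1 / rRef)
  if (!any(mask == 1)) return(mask)
  out <- if (radius >= 1)
    EBImage::dilate(mask, diskKernel(radius)) else mask
  if (fill) out <- EBImage::fillHull(out)
  unclass(out)
}
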