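## Model-independent local thickness of the nuclei mask. For a point p of
## the structure, tau(p) is the diameter of the largest disk that contains
## p and fits entirely inside the structure. The implementation follows the
## classic distance-map / distance-ridge decomposition: the Euclidean
## distance map gives, at each foreground pixel, the radius of the largest
## inscribed disk centred there; the ridge keeps only maximal
## (non-redundant) disks; tau is propagated from those.
##
## Conventions: images are single sections, so disks replace spheres.
## Distances are to the nearest background pixel *centre*, with everything
## outside the image frame counting as background, so a lone foreground
## pixel has d = 1 and tau = 2.

#' Euclidean distance map of a binary mask
#'
#' Exact Euclidean distance from each foreground pixel to the nearest
#' background pixel center; 0 on background. Pixels outside the frame
#' count as background.
#'
#' @param mask binary matrix.
#' @return numeric matrix of distances in px.
#' @export
distanceMap <- function(mask) {
  m <- (unclass(mask) != 0) * 1
  pad <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  d <- EBImage::distmap(pad, metric = "euclidean")
  unclass(d)[2:(nrow(m) + 1L), 2:(ncol(m) + 1L), drop = FALSE]
}

#' Distance ridge: maximal inscribed disks
#'
#' The inscribed disk at `p` has radius `d(p)`; it is redundant when some
#' other disk contains it, i.e. when a foreground `q` exists with
#' `|p - q| + d(p) <= d(q)`. The ridge is the set of non-redundant disks;
#' together they still cover every foreground pixel.
#'
#' @param dist distance map from [distanceMap()], or a binary mask.
#' @return data.frame with 1-based center coordinates `x`, `y` and
#'   `radius` (px), in scan order.
#' @export
distanceRidge <- function(dist) {
  d <- unclass(dist)
  if (all(d %in% c(0, 1)) && any(d == 1)) d <- distanceMap(d)
  r <- .cpp_ridge(d)
  idx <- which(r, arr.ind = TRUE)
  out <- data.frame(x = as.integer(idx[, 1]), y = as.integer(idx[, 2]),
                    radius = d[idx])
  out[order(out$y, out$x), , drop = FALSE]
}

#' Local thickness map
#'
#' `tau(p) = 2 * max{ r : p` inside an inscribed disk of radius `r }`,
#' computed by propagating diameters from the distance ridge. A pixel `p`
#' belongs to the disk at `x` when `|p - x| < d(x)`.
#'
#' @param mask binary matrix.
#' @return numeric matrix of thickness values in px; 0 on background.
#' @export
localThickness <- function(mask) {
  .cpp_thickness(distanceMap(mask))
}

#' Render a thickness map as an 8-bit image
#'
#' Absolute linear mapping
#' `intensity = clamp(round(255 * tau_um / tauDisplayMax), 0, 255)` with
#' `tau_um = tau * rRef`. The mapping is not per-image normalized, so
#' rendered tiles are comparable and the bright-pixel threshold has a fixed
#' physical meaning (at the defaults, intensity 221 is a thickness of about
#' 17.3 um, roughly two epithelial cell layers).
#'
#' @param tmap thickness map from [localThickness()].
#' @param rRef resolution in um/px.
#' @param tauDisplayMax thickness (um) rendered as full intensity 255.
#' @return integer matrix of 8-bit intensities.
#' @export
renderThickness <- function(tmap, rRef = 0.46, tauDisplayMax = 20) {
  if (tauDisplayMax <= 0) tmaError("tauDisplayMax must be positive", "tmaBadConfig")
  clamp8(roundHalfUp(255 * (unclass(tmap) * rRef) / tauDisplayMax))
}

#' Count bright pixels of a rendered thickness image
#'
#' Bright means intensity at least `brightFactor * pRef(profile)` (221 at
#' the default profile); bright pixels mark structures thick enough to be
#' a double cell layer.
#'
#' @param img 8-bit intensity matrix from [renderThickness()].
#' @param profile a [ReferenceProfile-class].
#' @param brightFactor multiple of `pRef` defining "bright".
#' @return integer count.
#' @export
countBright <- function(img, profile = ReferenceProfile(), brightFactor = 1.3) {
  sum(unclass(img) >= brightFactor * pRef(profile) - THRESH_EPS)
}

#' Single- vs double-layer decision
#'
#' More than `brightCountConst / rRef^2` bright pixels means thick (double
#' layer, unaffected epithelium); otherwise a single cell layer around the
#' lumen (affected).
#'
#' @param brightCount count from [countBright()].
#' @param rRef resolution in um/px.
#' @param brightCountConst threshold constant.
#' @return `"double_layer"` or `"single_layer"`.
#' @export
classifyLayering <- function(brightCount, rRef = 0.46, brightCountConst = 530) {
  if (brightCount > brightCountConst / rRef^2 + THRESH_EPS) "double_layer"
  else "single_layer"
}
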