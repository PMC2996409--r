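#' Reference intensity and resolution profile
#'
#' Anchors to which every slide is normalized before tiling and
#' classification: background (\code{bR}), nuclei (\code{nR}) and cytoplasm
#' (\code{cR}) mean gray levels, their mean \code{pRef}, and the reference
#' resolution \code{rRef} in micrometers per pixel. H&E ordering is
#' enforced: background brightest, nuclei darkest.
#'
#' @slot bR numeric(1), background reference intensity (8-bit gray).
#' @slot nR numeric(1), nuclei reference intensity (8-bit gray).
#' @slot cR numeric(1), cytoplasm reference intensity (8-bit gray).
#' @slot pRef numeric(1), mean reference intensity (8-bit gray).
#' @slot rRef numeric(1), reference resolution (micrometers per pixel).
#' @aliases ReferenceProfile-class
#' @exportClass ReferenceProfile
setClass("ReferenceProfile",
  representation(bR = "numeric", nR = "numeric", cR = "numeric",
                 pRef = "numeric", rRef = "numeric"))

setValidity("ReferenceProfile", function(object) {
  msg <- character()
  v <- c(object@bR, object@nR, object@cR, object@pRef)
  if (any(v < 0 | v > 255)) msg <- c(msg, "intensities must lie in [0, 255]")
  if (!(object@bR > object@cR && object@cR > object@nR))
    msg <- c(msg, "ordering bR > cR > nR violated")
  if (object@rRef <= 0) msg <- c(msg, "rRef must be positive")
  ## pRef is the rounded anchor mean; proportional rescaling of the anchors
  ## (deriveProfile) can shift the rounded mean by one gray level
  if (abs(object@pRef - roundHalfUp((object@bR + object@nR + object@cR) / 3)) > 1)
    msg <- c(msg, "pRef must equal the rounded mean of bR, nR, cR (within 1)")
  if (length(msg)) msg else TRUE
})

#' Create a reference profile
#'
#' Defaults describe the training conditions the thresholds were built on:
#' mean reference intensity 170 at 0.46 um/px, with anchors 235/175/100
#' whose mean is exactly 170.
#'
#' @param bR,cR,nR background / cytoplasm / nuclei reference gray levels.
#' @param pRef mean reference intensity; computed from the anchors when
#'   missing.
#' @param rRef reference resolution in um/px.
#' @return a [ReferenceProfile-class] object.
#' @examples
#' ReferenceProfile()
#' @export
ReferenceProfile <- function(bR = 235, cR = 175, nR = 100,
                             pRef = roundHalfUp((bR + nR + cR) / 3),
                             rRef = 0.46) {
  new("ReferenceProfile", bR = as.numeric(bR), nR = as.numeric(nR),
      cR = as.numeric(cR), pRef = as.numeric(pRef), rRef = as.numeric(rRef))
}

#' @describeIn ReferenceProfile-class mean reference intensity.
#' @param object,x a \code{ReferenceProfile}.
#' @export
setGeneric("pRef", function(object) standardGeneric("pRef"))
#' @rdname ReferenceProfile-class
#' @export
setMethod("pRef", "ReferenceProfile", function(object) object@pRef)

#' @describeIn ReferenceProfile-class reference resolution (um/px).
#' @export
setGeneric("rRef", function(object) standardGeneric("rRef"))
#' @rdname ReferenceProfile-class
#' @export
setMethod("rRef", "ReferenceProfile", function(object) object@rRef)

#' @describeIn ReferenceProfile-class the three anchors as a named vector
#'   (B, C, N).
#' @export
setGeneric("anchors", function(object) standardGeneric("anchors"))
#' @rdname ReferenceProfile-class
#' @export
setMethod("anchors", "ReferenceProfile",
          function(object) c(B = object@bR, C = object@cR, N = object@nR))

setMethod("show", "ReferenceProfile", function(object) {
  cat("ReferenceProfile\n",
      "  anchors (B/C/N): ", object@bR, "/", object@cR, "/", object@nR, "\n",
      "  pRef: ", object@pRef, "  rRef: ", object@rRef, " um/px\n", sep = "")
})

#' Punching grid over a slide
#'
#' Partition of a `width x height` image into `rows x cols` rectangular
#' tiles. Cell sizes use floor division; the last row and column absorb the
#' remainder pixels. Bounds are 0-based half-open `[x0, x1) x [y0, y1)`
#' rectangles in row-major order (row varies slowest).
#'
#' @slot rows,cols integer grid dimensions.
#' @slot width,height image dimensions in pixels.
#' @slot bounds integer matrix `rows*cols x 4` with columns x0, x1, y0, y1.
#' @aliases TmaGrid-class
#' @exportClass TmaGrid
setClass("TmaGrid",
  representation(rows = "integer", cols = "integer",
                 width = "integer", height = "integer",
                 bounds = "matrix"))

setValidity("TmaGrid", function(object) {
  b <- object@bounds
  if (nrow(b) != object@rows * object@cols)
    return("bounds must have rows*cols rows")
  area <- sum((b[, 2] - b[, 1]) * (b[, 4] - b[, 3]))
  if (area != as.numeric(object@width) * object@height)
    return("grid cells must partition the image")
  TRUE
})

setMethod("show", "TmaGrid", function(object) {
  cat("TmaGrid: ", object@rows, " x ", object@cols, " tiles over ",
      object@width, " x ", object@height, " px\n", sep = "")
})

#' @describeIn TmaGrid-class number of tiles.
#' @param object a \code{TmaGrid}.
#' @export
setGeneric("nTiles", function(object) standardGeneric("nTiles"))
#' @rdname TmaGrid-class
#' @export
setMethod("nTiles", "TmaGrid",
          function(object) as.integer(object@rows * object@cols))

#' Three-class color segmentation of a tile
#'
#' Disjoint binary masks covering every pixel: white (mucus/background),
#' pink (cytoplasm, basic), blue (nuclei, acid), ranked by cluster mean
#' luminance.
#'
#' @slot white,pink,blue logical matrices of identical dimension.
#' @aliases SegmentationResult-class
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(white = "matrix", pink = "matrix", blue = "matrix"))

setValidity("SegmentationResult", function(object) {
  s <- object@white + object@pink + object@blue
  if (!all(s == 1)) return("masks must be disjoint and cover every pixel")
  TRUE
})

#' @describeIn SegmentationResult-class mucus/background mask.
#' @param object a \code{SegmentationResult}.
#' @export
setGeneric("whiteMask", function(object) standardGeneric("whiteMask"))
#' @rdname SegmentationResult-class
#' @export
setMethod("whiteMask", "SegmentationResult", function(object) object@white)
#' @describeIn SegmentationResult-class cytoplasm mask.
#' @export
setGeneric("pinkMask", function(object) standardGeneric("pinkMask"))
#' @rdname SegmentationResult-class
#' @export
setMethod("pinkMask", "SegmentationResult", function(object) object@pink)
#' @describeIn SegmentationResult-class nuclei mask.
#' @export
setGeneric("blueMask", function(object) standardGeneric("blueMask"))
#' @rdname SegmentationResult-class
#' @export
setMethod("blueMask", "SegmentationResult", function(object) object@blue)

setMethod("show", "SegmentationResult", function(object) {
  d <- dim(object@white)
  cat("SegmentationResult ", d[1], " x ", d[2], " px: white ",
      sum(object@white), ", pink ", sum(object@pink), ", blue ",
      sum(object@blue), " px\n", sep = "")
})

#' Confusion matrix over affected-vs-unaffected tiles
#'
#' The positive class is "affected"; non-informative tiles are excluded
#' before counting.
#'
#' @slot tp,fp,fn,tn non-negative integer counts.
#' @aliases ConfusionMatrix-class
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(tp = "integer", fp = "integer",
                 fn = "integer", tn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(v < 0)) return("counts must be non-negative")
  TRUE
})

#' Build a ConfusionMatrix from counts
#'
#' @param tp,fp,fn,tn counts (positive class = affected).
#' @return a [ConfusionMatrix-class] object.
#' @examples ConfusionMatrix(541, 37, 101, 617)
#' @export
ConfusionMatrix <- function(tp, fp, fn, tn) {
  new("ConfusionMatrix", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn))
}

#' @describeIn ConfusionMatrix-class counts as a named vector.
#' @param object a \code{ConfusionMatrix}.
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname ConfusionMatrix-class
#' @export
setMethod("counts", "ConfusionMatrix", function(object)
  c(TP = object@tp, FP = object@fp, FN = object@fn, TN = object@tn))

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (positive = affected): TP=", object@tp,
      " FP=", object@fp, " FN=", object@fn, " TN=", object@tn, "\n",
      sep = "")
})
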