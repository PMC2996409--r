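## Stain-intensity calibration: a single quadratic transfer y = A x^2 + B x
## + C fitted on three luminance anchors (background, nuclei, cytoplasm) and
## applied to every RGB channel, followed by rescaling to the reference
## resolution. Both run once per whole slide, before tiling.

#' Estimate background, nuclei and cytoplasm gray levels of a slide
#'
#' Clusters pixel luminance into three groups (k-means, k = 3) and returns
#' the mean luminance of the brightest (B, background), darkest (N, nuclei)
#' and intermediate (C, cytoplasm) cluster. Initial centers sit at the
#' 10/50/90 percent quantiles of the distinct luminance values, which makes
#' the estimate deterministic without a seed. Slides larger than
#' `maxPixels` are subsampled with a deterministic even stride.
#'
#' @param image RGB [EBImage::Image] (or array) of the whole slide.
#' @param maxPixels maximum number of pixels fed to k-means.
#' @return named numeric vector `c(B=, C=, N=)` of 8-bit gray levels,
#'   `B > C > N`.
#' @seealso [solveTransfer()], [applyTransfer()]
#' @export
estimateColorLevels <- function(image, maxPixels = 2e5) {
  lum <- as.vector(luminance8(image))
  if (length(lum) > maxPixels) {
    idx <- unique(roundHalfUp(seq(1, length(lum), length.out = maxPixels)))
    lum <- lum[idx]
  }
  u <- sort(unique(lum))
  if (length(u) < 3)
    tmaError("image has fewer than 3 distinct gray levels", "tmaDegenerateImage")
  centers <- quantile(u, c(0.1, 0.5, 0.9), names = FALSE, type = 1)
  if (anyDuplicated(centers))
    centers <- u[roundHalfUp(c(1, (length(u) + 1) / 2, length(u)))]
  km <- kmeans(lum, centers = matrix(centers, ncol = 1), iter.max = 100)
  means <- sort(as.vector(km$centers), decreasing = TRUE)
  c(B = means[1], C = means[2], N = means[3])
}

#' Solve the quadratic transfer through the three anchor pairs
#'
#' Finds the unique quadratic `y = A x^2 + B x + C` mapping the observed
#' anchors (B, N, C gray levels) onto the reference anchors exactly.
#'
#' @param observed named vector with elements `B`, `C`, `N` as returned by
#'   [estimateColorLevels()].
#' @param reference a [ReferenceProfile-class].
#' @return named numeric `c(A=, B=, C=)`, the calibration coefficients.
#' @examples
#' solveTransfer(c(B = 235, C = 175, N = 100), ReferenceProfile())
#' @export
solveTransfer <- function(observed, reference) {
  x <- as.numeric(observed[c("B", "N", "C")])
  y <- c(reference@bR, reference@nR, reference@cR)
  if (anyDuplicated(x))
    tmaError("observed anchors must be pairwise distinct", "tmaSingularSystem")
  m <- cbind(x^2, x, 1)
  co <- unname(solve(m, y))
  c(A = co[1], B = co[2], C = co[3])
}

#' Apply a calibration transfer to an image
#'
#' Every 8-bit channel value `v` becomes
#' `clamp(round(A v^2 + B v + C), 0, 255)` (round half up). One shared
#' coefficient set acts on all channels.
#'
#' @param image RGB [EBImage::Image] or array.
#' @param coeffs coefficients from [solveTransfer()].
#' @return calibrated image of identical dimensions.
#' @export
applyTransfer <- function(image, coeffs) {
  v <- pixels8(image)
  y <- coeffs[["A"]] * v^2 + coeffs[["B"]] * v + coeffs[["C"]]
  image8(roundHalfUp(y))
}

#' Rescale an image to the reference resolution
#'
#' Bilinear resampling to side lengths `round(size * rIn / rRef)` so that
#' one pixel spans `rRef` micrometers afterwards.
#'
#' @param image RGB [EBImage::Image] or array.
#' @param rIn acquisition resolution of `image`, in um/px.
#' @param profile a [ReferenceProfile-class] supplying `rRef`.
#' @return resized image.
#' @export
rescaleToResolution <- function(image, rIn, profile) {
  if (!is.numeric(rIn) || length(rIn) != 1 || rIn <= 0)
    tmaError("resolution must be a positive scalar (um/px)", "tmaInvalidResolution")
  img <- if (is(image, "Image")) image else
    EBImage::Image(image, colormode = if (length(dim(image)) == 3L) "Color" else "Grayscale")
  d <- dim(img)
  f <- rIn / rRef(profile)
  w <- roundHalfUp(d[1] * f); h <- roundHalfUp(d[2] * f)
  if (w == d[1] && h == d[2]) return(img)
  EBImage::resize(img, w = w, h = h, filter = "bilinear")
}

#' Derive a reference profile for a new mean intensity
#'
#' Rescales the three anchors proportionally so the profile keeps the
#' proportions of the original training conditions, with `pRef` set to
#' `pNew` and `bR` capped at 255.
#'
#' @param pNew new mean reference intensity, in `(0, 255]`.
#' @param base profile to rescale (default [ReferenceProfile()]).
#' @return a new [ReferenceProfile-class].
#' @examples
#' deriveProfile(85)
#' @export
deriveProfile <- function(pNew, base = ReferenceProfile()) {
  if (!is.numeric(pNew) || length(pNew) != 1 || pNew <= 0 || pNew > 255)
    tmaError("pNew must lie in (0, 255]", "tmaInvalidIntensity")
  f <- pNew / pRef(base)
  ReferenceProfile(bR = min(255, roundHalfUp(base@bR * f)),
                   cR = roundHalfUp(base@cR * f),
                   nR = roundHalfUp(base@nR * f),
                   pRef = pNew, rRef = rRef(base))
}

#' Read / write a reference profile as flat JSON
#'
#' Serialized as `{b_r, n_r, c_r, p_ref, r_ref}`.
#'
#' @param path file path.
#' @param profile a [ReferenceProfile-class].
#' @return `readProfile` returns a [ReferenceProfile-class];
#'   `writeProfile` returns `path` invisibly.
#' @export
readProfile <- function(path) {
  j <- read_json(path, simplifyVector = TRUE)
  ReferenceProfile(bR = j$b_r, cR = j$c_r, nR = j$n_r,
                   pRef = j$p_ref, rRef = j$r_ref)
}

#' @rdname readProfile
#' @export
writeProfile <- function(profile, path) {
  write_json(list(b_r = profile@bR, n_r = profile@nR, c_r = profile@cR,
                  p_ref = profile@pRef, r_ref = profile@rRef),
             path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Calibrate a whole slide against a reference profile
#'
#' Convenience wrapper: estimate color levels, solve the transfer, apply
#' it. Returns the calibrated image; degenerate slides (fewer than three
#' gray levels) are returned unchanged with attribute
#' `calibration = "skipped"`.
#'
#' @inheritParams applyTransfer
#' @param profile a [ReferenceProfile-class].
#' @return calibrated RGB image.
#' @export
calibrateSlide <- function(image, profile = ReferenceProfile()) {
  levels <- tryCatch(estimateColorLevels(image),
                     tmaDegenerateImage = function(e) NULL)
  if (is.null(levels)) {
    img <- if (is(image, "Image")) image else image8(pixels8(image))
    attr(img, "calibration") <- "skipped"
    return(img)
  }
  applyTransfer(image, solveTransfer(levels, profile))
}
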