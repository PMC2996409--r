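## Ellipse morphometry of nuclear agglomerates. Each 8-connected component
## is summarized by its moment-equivalent ellipse; areas are pi*a*b of that
## ellipse (component pixel counts are kept as a diagnostic only). A size
## filter removes lymphocyte-sized objects before the area spread is used
## to call the tile's distribution random or structured.

#' Fit moment-equivalent ellipses to mask components
#'
#' One ellipse per 8-connected component, from second central moments, in
#' scan order of the first component pixel.
#'
#' @param mask binary matrix.
#' @return data.frame with columns `label`, `cx`, `cy`, `semimajor`,
#'   `semiminor`, `area` (`pi * semimajor * semiminor`, px^2) and
#'   `npixels`. Empty mask gives zero rows. Components of fewer than a few
#'   pixels can yield degenerate (zero) axes; the lymphocyte filter removes
#'   them downstream.
#' @export
fitEllipses <- function(mask) {
  m <- matrix(as.integer(unclass(mask) != 0), nrow = nrow(mask))
  lab <- .cpp_label8(m)
  n <- max(lab)
  empty <- data.frame(label = integer(), cx = numeric(), cy = numeric(),
                      semimajor = numeric(), semiminor = numeric(),
                      area = numeric(), npixels = integer())
  if (n == 0) return(empty)
  f <- EBImage::computeFeatures.moment(lab)
  f <- matrix(f, ncol = 5, dimnames = list(NULL, colnames(f)))
  a <- f[, "m.majoraxis"] / 2
  b <- a * sqrt(pmax(0, 1 - f[, "m.eccentricity"]^2))
  data.frame(label = seq_len(n), cx = f[, "m.cx"], cy = f[, "m.cy"],
             semimajor = a, semiminor = b, area = pi * a * b,
             npixels = tabulate(lab[lab > 0], nbins = n))
}

#' Drop lymphocyte-sized objects
#'
#' Keeps ellipses with area at least `sizeConst / rRef^2` px^2. The
#' default constant corresponds to the footprint of a typical lymphocyte
#' (about 8 um across), so single immune cells in inflamed tissue do not
#' masquerade as tubules.
#'
#' @param ellipses data.frame from [fitEllipses()].
#' @param rRef resolution in um/px.
#' @param sizeConst size-filter constant (um^2-denominated).
#' @return filtered data.frame.
#' @export
filterLymphocyteSized <- function(ellipses, rRef = 0.46, sizeConst = 64) {
  if (rRef <= 0) tmaError("rRef must be positive", "tmaInvalidResolution")
  ellipses[ellipses$area >= sizeConst / rRef^2 - THRESH_EPS, , drop = FALSE]
}

#' Population standard deviation of ellipse areas
#'
#' Describes the size spread of the agglomerates in one tile, hence the
#' population (not sample) formula.
#'
#' @param ellipses data.frame from [fitEllipses()], or a numeric vector of
#'   areas.
#' @return standard deviation in px^2; a single object gives 0.
#' @export
areaStd <- function(ellipses) {
  a <- if (is.data.frame(ellipses)) ellipses$area else as.numeric(ellipses)
  if (length(a) == 0)
    tmaError("standard deviation undefined for an empty object set",
             "tmaUndefinedStatistic")
  sqrt(mean((a - mean(a))^2))
}

#' Classify the agglomerate size distribution
#'
#' Pathological (tubular-carcinoma) tiles hold many small, size-homogeneous
#' tubules, normal tiles few large, size-heterogeneous lobules; the area
#' standard deviation separates the two. Below `stdConst / rRef^2` the
#' distribution is called `random` (pathological), at or above it
#' `structured`.
#'
#' @param std area standard deviation in px^2.
#' @param rRef resolution in um/px.
#' @param stdConst threshold constant (um^2-denominated).
#' @return `"random"` or `"structured"`.
#' @export
classifyDistribution <- function(std, rRef = 0.46, stdConst = 95) {
  if (std < stdConst / rRef^2 - THRESH_EPS) "random" else "structured"
}
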