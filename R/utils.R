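## Shared numeric helpers. All 8-bit arithmetic in the package rounds half
## away from zero ("round half up") so that integer images are reproducible
## across platforms; base round() would round half to even.

#' Round half up
#'
#' @param x numeric vector.
#' @return `floor(x + 0.5)`, the convention used for every 8-bit conversion
#'   in the package.
#' @examples roundHalfUp(c(0.5, 1.5, 50.5))
#' @export
roundHalfUp <- function(x) floor(x + 0.5)

clamp8 <- function(x) pmin(pmax(x, 0), 255)

## Comparison slack for thresholds built from decimal factors (1.2, 1.3):
## 1.3 * 170 is 221.0000000000000284 in double precision, and a pixel at
## exactly 221 must count as bright.
THRESH_EPS <- 1e-6

#' Luminance of an 8-bit RGB array
#'
#' Rec. 601 luma: `0.299 R + 0.587 G + 0.114 B`, computed on the 0..255
#' scale.
#'
#' @param img an [EBImage::Image] in Color mode, or a `width x height x 3`
#'   array with values in `[0, 1]`.
#' @return a `width x height` matrix of luminance values in `[0, 255]`.
#' @export
luminance8 <- function(img) {
  a <- pixels8(img)
  if (length(dim(a)) == 2L) return(a)
  0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
}

## EBImage images hold doubles in [0,1]; the algorithms are specified on
## 8-bit integers. pixels8/image8 convert back and forth.
pixels8 <- function(img) {
  a <- if (is(img, "Image")) EBImage::imageData(img) else img
  a <- unclass(a)
  if (length(dim(a)) == 3L && dim(a)[3] != 3L)
    stop("expected a 3-channel RGB image")
  roundHalfUp(a * 255)
}

image8 <- function(a8) {
  EBImage::Image(clamp8(a8) / 255,
                 colormode = if (length(dim(a8)) == 3L) "Color" else "Grayscale")
}

tmaError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tmaError")))
}

## restore the RNG state on exit so seeded internals do not disturb the
## caller's stream
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
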