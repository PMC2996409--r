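## Punching-grid tiling. Tiles are reported 1-based as (row, column), rows
## spanning the image height and columns the width, matching how annotated
## overview images are read.

#' Build a punching grid
#'
#' Cell sizes come from floor division; the last row and column absorb the
#' remainder pixels so all other cells are uniform. The defaults give the
#' 8 x 9 punching grid used for whole-slide screening.
#'
#' @param width,height image dimensions in pixels.
#' @param rows,cols grid dimensions.
#' @return a [TmaGrid-class].
#' @examples
#' makeGrid(6720, 4200)        # 72 tiles
#' @export
makeGrid <- function(width, height, rows = 8, cols = 9) {
  width <- as.integer(width); height <- as.integer(height)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1 || cols < 1 || rows > height || cols > width)
    tmaError("grid dimensions exceed image size", "tmaBadGrid")
  bw <- width %/% cols; bh <- height %/% rows
  x0 <- (seq_len(cols) - 1L) * bw
  x1 <- c(x0[-1L], width)
  y0 <- (seq_len(rows) - 1L) * bh
  y1 <- c(y0[-1L], height)
  bounds <- cbind(x0 = rep(x0, times = rows), x1 = rep(x1, times = rows),
                  y0 = rep(y0, each = cols), y1 = rep(y1, each = cols))
  new("TmaGrid", rows = rows, cols = cols, width = width, height = height,
      bounds = bounds)
}

#' Tile bounds as a data.frame
#'
#' @param grid a [TmaGrid-class].
#' @return data.frame with 1-based `row`, `col` and 0-based half-open pixel
#'   bounds `x0, x1, y0, y1`, in row-major order.
#' @export
tileBounds <- function(grid) {
  data.frame(row = rep(seq_len(grid@rows), each = grid@cols),
             col = rep(seq_len(grid@cols), times = grid@rows),
             grid@bounds)
}

#' Cut a slide into tiles
#'
#' @param image RGB [EBImage::Image] or array.
#' @param grid a [TmaGrid-class] built for this image size.
#' @return list of tile images in row-major order (length `rows * cols`);
#'   concatenating them reproduces the image pixel for pixel.
#' @export
cutTiles <- function(image, grid) {
  a <- if (is(image, "Image")) EBImage::imageData(image) else image
  d <- dim(a)
  if (d[1] != grid@width || d[2] != grid@height)
    tmaError("grid was built for a different image size", "tmaGridMismatch")
  color <- length(d) == 3L
  lapply(seq_len(nrow(grid@bounds)), function(i) {
    b <- grid@bounds[i, ]
    sub <- if (color) a[(b[1] + 1):b[2], (b[3] + 1):b[4], , drop = FALSE]
           else a[(b[1] + 1):b[2], (b[3] + 1):b[4], drop = FALSE]
    EBImage::Image(sub, colormode = if (color) "Color" else "Grayscale")
  })
}

labelBorderColors <- function() {
  list(affected = c(255, 0, 0), unaffected = c(0, 200, 0),
       non_informative = c(128, 128, 128))
}

#' Reassemble labelled tiles into an annotated overview
#'
#' Draws a border (default 5 px, inside each tile) colored by verdict:
#' red = affected, green = unaffected, gray = non-informative.
#'
#' @param tiles list of tiles from [cutTiles()], row-major.
#' @param labels character vector, one of `affected`, `unaffected`,
#'   `non_informative` per tile.
#' @param grid the [TmaGrid-class] the tiles came from.
#' @param borderWidth border width in pixels.
#' @return RGB [EBImage::Image] of the original slide dimensions.
#' @export
annotateAndReassemble <- function(tiles, labels, grid, borderWidth = 5) {
  if (length(tiles) != nTiles(grid) || length(labels) != nTiles(grid))
    tmaError("one tile and one label per grid cell required", "tmaLabelMismatch")
  bad <- setdiff(unique(labels), names(labelBorderColors()))
  if (length(bad))
    tmaError(paste("unknown labels:", paste(bad, collapse = ", ")),
             "tmaLabelMismatch")
  canvas <- array(0, dim = c(grid@width, grid@height, 3))
  cols3 <- labelBorderColors()
  for (i in seq_along(tiles)) {
    b <- grid@bounds[i, ]
    a <- pixels8(tiles[[i]])
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
    w <- dim(a)[1]; h <- dim(a)[2]
    bw <- min(borderWidth, ceiling(w / 2), ceiling(h / 2))
    rim <- c(seq_len(bw), w - seq_len(bw) + 1L)
    col <- cols3[[labels[i]]]
    for (ch in 1:3) {
      a[rim, , ch] <- col[ch]
      a[, c(seq_len(bw), h - seq_len(bw) + 1L), ch] <- col[ch]
    }
    canvas[(b[1] + 1):b[2], (b[3] + 1):b[4], ] <- a
  }
  image8(canvas)
}

#' Reassemble tiles without annotation
#'
#' Identity counterpart of [cutTiles()]; mainly used to verify the
#' partition property.
#'
#' @inheritParams annotateAndReassemble
#' @return RGB or grayscale [EBImage::Image] of the original dimensions.
#' @export
reassembleTiles <- function(tiles, grid) {
  if (length(tiles) != nTiles(grid))
    tmaError("one tile per grid cell required", "tmaLabelMismatch")
  d1 <- dim(EBImage::imageData(tiles[[1]]))
  color <- length(d1) == 3L
  canvas <- if (color) array(0, dim = c(grid@width, grid@height, 3))
            else array(0, dim = c(grid@width, grid@height))
  for (i in seq_along(tiles)) {
    b <- grid@bounds[i, ]
    a <- EBImage::imageData(tiles[[i]])
    if (color) canvas[(b[1] + 1):b[2], (b[3] + 1):b[4], ] <- a
    else canvas[(b[1] + 1):b[2], (b[3] + 1):b[4]] <- a
  }
  EBImage::Image(canvas, colormode = if (color) "Color" else "Grayscale")
}
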