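test_that("color levels recover the three patch tones, noisy or not", {
  img <- grayPatchImage(c(235, 175, 100))
  lv <- estimateColorLevels(img)
  expect_equal(unname(lv), c(235, 175, 100))
  expect_true(lv[["B"]] > lv[["C"]] && lv[["C"]] > lv[["N"]])

  # per-patch means are the oracle for the noisy case
  set.seed(42)
  a <- EBImage::imageData(img) * 255
  noisy <- pmin(pmax(a + rnorm(length(a), 0, 3), 0), 255)
  lvN <- estimateColorLevels(EBImage::Image(round(noisy) / 255,
                                            colormode = "Color"))
  expect_lt(max(abs(lvN - c(235, 175, 100))), 2)
})

test_that("degenerate images are rejected", {
  flat <- EBImage::Image(array(1, c(10, 10, 3)), colormode = "Color")
  expect_error(estimateColorLevels(flat), class = "tmaDegenerateImage")
  two <- grayPatchImage(c(200, 200, 50))
  expect_error(estimateColorLevels(two), class = "tmaDegenerateImage")
})

test_that("transfer solving matches Lagrange interpolation and handles ties", {
  ref <- ReferenceProfile()
  expect_equal(unname(solveTransfer(anchors(ref)[c("B", "C", "N")], ref)),
               c(0, 1, 0), tolerance = 1e-12)

  # quadratic through (0,0), (1,2), (2,6) is x^2 + x
  refB <- ReferenceProfile(bR = 6, cR = 2, nR = 0, pRef = 3, rRef = 1)
  co <- solveTransfer(c(B = 2, C = 1, N = 0), refB)
  expect_equal(unname(co), c(1, 1, 0), tolerance = 1e-12)

  # independent oracle: Lagrange basis interpolation through the 3 anchors
  obs <- c(B = 200, N = 90, C = 160)
  co2 <- solveTransfer(obs, ref)
  lagrange <- function(x, xs, ys) {
    sum(vapply(1:3, function(i)
      ys[i] * prod((x - xs[-i]) / (xs[i] - xs[-i])), numeric(1)))
  }
  xs <- c(200, 90, 160); ys <- c(235, 100, 175)
  for (x in c(0, 90, 128, 160, 200, 255)) {
    expect_equal(co2[["A"]] * x^2 + co2[["B"]] * x + co2[["C"]],
                 lagrange(x, xs, ys), tolerance = 1e-8)
  }
  expect_error(solveTransfer(c(B = 200, N = 200, C = 160), ref),
               class = "tmaSingularSystem")
})

test_that("applying a transfer clamps, rounds half up and keeps dimensions", {
  img <- grayPatchImage(c(250, 100, 10))
  idcoef <- c(A = 0, B = 1, C = 0)
  expect_equal(EBImage::imageData(applyTransfer(img, idcoef)),
               EBImage::imageData(img))
  shifted <- applyTransfer(img, c(A = 0, B = 1, C = 10))
  expect_equal(max(EBImage::imageData(shifted)) * 255, 255)   # 250 clamped
  quad <- applyTransfer(grayPatchImage(c(10, 5, 0)), c(A = 1, B = 1, C = 0))
  expect_equal(max(round(EBImage::imageData(quad) * 255)), 110)  # 100 + 10
})

test_that("calibration round-trips onto the reference anchors and is idempotent", {
  ref <- ReferenceProfile()
  img <- grayPatchImage(c(200, 150, 80))
  cal <- applyTransfer(img, solveTransfer(estimateColorLevels(img), ref))
  lv <- estimateColorLevels(cal)
  expect_lt(max(abs(lv - c(235, 175, 100))), 2)
  # calibrating again moves nothing by more than one gray level
  cal2 <- applyTransfer(cal, solveTransfer(estimateColorLevels(cal), ref))
  expect_lte(max(abs(round(EBImage::imageData(cal2) * 255) -
                     round(EBImage::imageData(cal) * 255))), 1)
})

test_that("resolution rescaling follows round-half-up and keeps aspect ratio", {
  ref <- ReferenceProfile()
  img <- EBImage::Image(array(runif(100 * 100 * 3), c(100, 100, 3)),
                        colormode = "Color")
  out <- rescaleToResolution(img, 0.23, ref)
  expect_equal(dim(out)[1:2], c(50, 50))
  img2 <- EBImage::Image(array(runif(101 * 101 * 3), c(101, 101, 3)),
                         colormode = "Color")
  expect_equal(dim(rescaleToResolution(img2, 0.23, ref))[1:2], c(51, 51))
  expect_equal(dim(rescaleToResolution(img, 0.46, ref))[1:2], c(100, 100))
  rect <- EBImage::Image(array(runif(200 * 100 * 3), c(200, 100, 3)),
                         colormode = "Color")
  d <- dim(rescaleToResolution(rect, 0.3, ref))[1:2]
  expect_lte(abs(d[1] / d[2] - 2), 2 / d[2])   # aspect within one pixel
  expect_error(rescaleToResolution(img, -1, ref),
               class = "tmaInvalidResolution")
})

test_that("derived profiles keep the anchor proportions", {
  base <- ReferenceProfile()
  expect_equal(anchors(deriveProfile(170, base)), anchors(base))
  half <- deriveProfile(85, base)
  expect_equal(unname(anchors(half)), c(118, 88, 50))
  expect_equal(pRef(half), 85)
  expect_error(deriveProfile(0, base), class = "tmaInvalidIntensity")
  expect_error(deriveProfile(300, base), class = "tmaInvalidIntensity")
})

test_that("profiles serialize to flat JSON and back", {
  p <- ReferenceProfile(bR = 220, cR = 160, nR = 95, rRef = 0.23)
  path <- withr::local_tempfile(fileext = ".json")
  writeProfile(p, path)
  q <- readProfile(path)
  expect_equal(anchors(q), anchors(p))
  expect_equal(pRef(q), pRef(p))
  expect_equal(rRef(q), rRef(p))
})
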