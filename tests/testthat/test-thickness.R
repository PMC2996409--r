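test_that("the distance map is the exact EDT with the frame as background", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  expect_equal(distanceMap(m)[3, 3], 1)
  sq <- matrix(0, 9, 9); sq[3:7, 3:7] <- 1
  d <- distanceMap(sq)
  expect_equal(d[5, 5], 3)                  # centre of a 5x5 solid square
  expect_equal(distanceMap(matrix(0, 6, 6)), matrix(0, 6, 6))
  set.seed(3)
  for (k in 1:10) {
    msk <- randomMask(20, 20)
    expect_equal(distanceMap(msk), bfDistanceMap(msk), tolerance = 1e-9)
  }
})

test_that("the distance ridge keeps exactly the maximal disks", {
  # solid disk: ridge agrees with the all-pairs containment oracle and
  # its largest disk sits at the centre
  dk <- diskMask(21, 8)
  r <- distanceRidge(distanceMap(dk))
  rw <- bfRidge(dk)
  expect_equal(r[order(r$x, r$y), c("x", "y", "radius")],
               rw[order(rw$x, rw$y), ], ignore_attr = TRUE)
  top <- r[which.max(r$radius), ]
  expect_equal(c(top$x, top$y), c(11, 11))
  # 1-px line: every pixel is its own maximal disk of radius 1
  ln <- matrix(0, 12, 7); ln[2:11, 4] <- 1
  rl <- distanceRidge(distanceMap(ln))
  expect_equal(nrow(rl), 10)
  expect_true(all(rl$radius == 1))
  expect_equal(nrow(distanceRidge(matrix(0, 8, 8))), 0)
  # brute-force containment oracle on random masks
  set.seed(9)
  for (k in 1:10) {
    msk <- randomMask(18, 18, ndisks = 3)
    got <- distanceRidge(distanceMap(msk))
    want <- bfRidge(msk)
    expect_equal(got[order(got$x, got$y), c("x", "y", "radius")],
                 want[order(want$x, want$y), ], ignore_attr = TRUE)
  }
  # every foreground pixel is covered by at least one ridge disk
  set.seed(10)
  msk <- randomMask(24, 24)
  rd <- distanceRidge(distanceMap(msk))
  fg <- which(msk == 1, arr.ind = TRUE)
  covered <- vapply(seq_len(nrow(fg)), function(i)
    any((rd$x - fg[i, 1])^2 + (rd$y - fg[i, 2])^2 < rd$radius^2 - 1e-9 |
        (rd$x == fg[i, 1] & rd$y == fg[i, 2])), logical(1))
  expect_true(all(covered))
})

test_that("local thickness matches closed forms", {
  dk <- diskMask(25, 8)
  expect_lt(abs(max(localThickness(dk)) - 16), 1)
  rect <- matrix(0, 50, 20); rect[6:45, 6:15] <- 1      # 40 x 10 strip
  tau <- localThickness(rect)
  expect_lt(abs(tau[25, 10] - 10), 1)
  expect_equal(localThickness(matrix(0, 10, 10)), matrix(0, 10, 10))
})

test_that("local thickness equals the exhaustive inscribed-disk oracle", {
  set.seed(21)
  for (k in 1:25) {
    msk <- randomMask(32, 32, ndisks = sample(2:6, 1))
    expect_equal(localThickness(msk), bfThickness(msk), tolerance = 1e-9)
  }
})

test_that("thickness is monotone under mask growth", {
  set.seed(33)
  for (k in 1:5) {
    a <- randomMask(28, 28, ndisks = 3)
    b <- pmax(a, randomMask(28, 28, ndisks = 2))
    expect_true(all(localThickness(b) >= localThickness(a) - 1e-9))
  }
})

test_that("rendering maps physical thickness linearly and absolutely", {
  expect_equal(renderThickness(matrix(0, 3, 3), 0.46, 20), matrix(0, 3, 3))
  tmap <- matrix(20 / 0.46)            # tau * rRef == tauDisplayMax
  expect_equal(renderThickness(tmap, 0.46, 20)[1, 1], 255)
  expect_equal(renderThickness(matrix(10 / 0.46), 0.46, 20)[1, 1], 128)
  expect_equal(renderThickness(matrix(100), 0.46, 20)[1, 1], 255)  # clamped
  expect_error(renderThickness(matrix(1), 0.46, 0), class = "tmaBadConfig")
})

test_that("bright pixels are counted at >= 1.3 * pRef, 221 included", {
  p <- ReferenceProfile()
  expect_equal(countBright(matrix(0, 10, 10), p), 0)
  img <- matrix(0, 10, 10); img[1:10] <- 255
  expect_equal(countBright(img, p), 10)
  edge <- matrix(c(220, 221, 222), 1)
  expect_equal(countBright(edge, p), 2)
})

test_that("layering needs strictly more than 530 / rRef^2 bright pixels", {
  cutoff <- 530 / 0.46^2                        # ~2504.7
  expect_equal(classifyLayering(0, 0.46), "single_layer")
  expect_equal(classifyLayering(floor(cutoff), 0.46), "single_layer")
  expect_equal(classifyLayering(ceiling(cutoff), 0.46), "double_layer")
})

test_that("double-ring walls outshine single-ring walls of the same lumen", {
  px <- 1 / 0.46
  lum <- 10 * px
  single <- diskMask(121, lum + 8 * px) - diskMask(121, lum)
  double <- diskMask(121, lum + 16 * px) - diskMask(121, lum)
  p <- ReferenceProfile()
  bright <- function(m) {
    dil <- cleanMask(m, rRef = 0.46, fill = FALSE)
    countBright(renderThickness(localThickness(dil), 0.46, 20), p)
  }
  bs <- bright(single); bd <- bright(double)
  expect_equal(bs, 0)                  # one cell layer is never "bright"
  expect_gt(bd, bs)
  expect_gt(bd, 530 / 0.46^2)          # a double layer alone crosses the cut
})
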