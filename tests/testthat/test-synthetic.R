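test_that("scene generation is deterministic per seed", {
  spec <- testSceneSpec(seed = 3)
  s1 <- generateScene(spec)
  s2 <- generateScene(spec)
  expect_identical(EBImage::imageData(s1$image), EBImage::imageData(s2$image))
  expect_identical(s1$truth, s2$truth)
  s3 <- generateScene(testSceneSpec(seed = 4))
  expect_false(identical(EBImage::imageData(s1$image),
                         EBImage::imageData(s3$image)))
})

test_that("the class plan is honored and matches the truth table", {
  plan <- matrix(c("fat", "normal", "pathological",
                   "normal", "fat", "pathological",
                   "pathological", "normal", "fat"),
                 3, 3, byrow = TRUE)
  spec <- testSceneSpec(seed = 6); spec$classPlan <- plan
  sc <- generateScene(spec)
  expect_equal(sc$truth$class, as.vector(t(plan)))
  expect_equal(sc$truth$label,
               unname(c(fat = "non_informative", normal = "unaffected",
                        pathological = "affected")[sc$truth$class]))
  expect_equal(nrow(sc$truth), 9)
  expect_equal(sc$truth$row, rep(1:3, each = 3))
  expect_equal(sc$truth$col, rep(1:3, 3))
})

test_that("fat tiles are bright, tissue tiles are not", {
  spec <- testSceneSpec(seed = 2)
  lum <- function(tile) mean(luminance8(tile))
  p <- ReferenceProfile()
  cut <- 1.2 * pRef(p)                      # 204
  expect_gt(lum(generateTile("fat", 448, 448, spec, seed = 1)), cut)
  expect_lt(lum(generateTile("normal", 448, 448, spec, seed = 1)), cut)
  expect_lt(lum(generateTile("pathological", 448, 448, spec, seed = 1,
                             variant = "random")), cut)
})

test_that("sampled class mixes follow the requested proportions", {
  spec <- sceneSpec(width = 60, height = 60, rows = 3, cols = 3,
                    mix = c(normal = 0.2, pathological = 0.5, fat = 0.3))
  ds <- generateLabeledDataset(60, spec, seed = 8, render = FALSE)
  classes <- unlist(lapply(ds, function(s) s$truth$class))
  expect_length(classes, 540)
  frac <- table(factor(classes, c("normal", "pathological", "fat"))) / 540
  # 3-sigma binomial bands around the requested proportions
  expect_lt(abs(frac[["normal"]] - 0.2), 3 * sqrt(0.2 * 0.8 / 540))
  expect_lt(abs(frac[["pathological"]] - 0.5), 3 * sqrt(0.25 / 540))
  expect_lt(abs(frac[["fat"]] - 0.3), 3 * sqrt(0.3 * 0.7 / 540))
})

test_that("discordant dropout leaves the advertised scorable count", {
  spec <- sceneSpec()                       # 8 x 9 grid
  ds <- generateLabeledDataset(20, spec, seed = 0, dropout = 0.1,
                               render = FALSE)
  total <- 20 * 72
  dropped <- sum(unlist(lapply(ds, function(s) s$truth$discordant)))
  expect_equal(dropped, 144)                # round(0.1 * 1440)
  expect_equal(attr(ds, "scorable"), total - dropped)
  expect_equal(attr(ds, "scorable"), 1296)
  # truth-only mode matches the rendered class sequence
  dr <- generateLabeledDataset(2, testSceneSpec(), seed = 5, render = TRUE)
  dn <- generateLabeledDataset(2, testSceneSpec(), seed = 5, render = FALSE)
  for (s in 1:2) {
    expect_equal(dn[[s]]$truth$class, dr[[s]]$truth$class)
    expect_equal(dn[[s]]$truth$discordant, dr[[s]]$truth$discordant)
  }
  expect_error(generateLabeledDataset(1, spec, dropout = 1),
               class = "tmaBadSpec")
})

test_that("the two pathological variants separate on area spread", {
  spec <- testSceneSpec(seed = 7)
  p <- ReferenceProfile()
  spread <- function(variant) {
    tile <- generateTile("pathological", 448, 448, spec, seed = 11,
                         variant = variant)
    seg <- segmentTile(tile, seed = 0)
    msk <- cleanMask(nucleiMask(tile, seg), rRef = 0.46)
    ell <- filterLymphocyteSized(fitEllipses(EBImage::fillHull(msk)),
                                 rRef = 0.46)
    areaStd(ell$area)
  }
  expect_lt(spread("random"), 95 / 0.46^2)
  expect_gte(spread("single_layer"), 95 / 0.46^2)
})
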