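## Independent brute-force oracles and small fixture builders. Everything
## here is deliberately naive (all-pairs searches, direct rasterization) so
## the implementation under test shares no code path with its oracle.

## exact distance to the nearest background pixel centre, counting
## everything outside the frame as background (virtual 1-px ring)
bfDistanceMap <- function(mask) {
  w <- nrow(mask); h <- ncol(mask)
  d <- matrix(0, w, h)
  fg <- which(mask == 1, arr.ind = TRUE)
  if (nrow(fg) == 0) return(d)
  ringx <- c(rep(0:(w + 1), 2), rep(c(0, w + 1), each = h))
  ringy <- c(rep(c(0, h + 1), each = w + 2), rep(1:h, 2))
  bgIn <- which(mask == 0, arr.ind = TRUE)
  bx <- c(bgIn[, 1], ringx); by <- c(bgIn[, 2], ringy)
  for (i in seq_len(nrow(fg))) {
    d[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bx - fg[i, 1])^2 + (by - fg[i, 2])^2))
  }
  d
}

## tau(p) = 2 max{ d(x) : |p-x|^2 < d(x)^2 } by exhaustive search over all
## candidate centres x
bfThickness <- function(mask) {
  d <- bfDistanceMap(mask)
  tau <- matrix(0, nrow(mask), ncol(mask))
  fg <- which(mask == 1, arr.ind = TRUE)
  if (nrow(fg) == 0) return(tau)
  dv <- d[fg]
  for (i in seq_len(nrow(fg))) {
    dist2 <- (fg[, 1] - fg[i, 1])^2 + (fg[, 2] - fg[i, 2])^2
    tau[fg[i, 1], fg[i, 2]] <- 2 * max(dv[dist2 < dv^2 - 1e-9 |
                                            (dist2 == 0 & dv > 0)])
  }
  tau
}

## non-redundant inscribed disks by all-pairs containment
bfRidge <- function(mask) {
  d <- bfDistanceMap(mask)
  fg <- which(mask == 1, arr.ind = TRUE)
  keep <- logical(nrow(fg))
  dv <- d[fg]
  for (i in seq_len(nrow(fg))) {
    dist <- sqrt((fg[, 1] - fg[i, 1])^2 + (fg[, 2] - fg[i, 2])^2)
    contained <- dist + dv[i] <= dv + 1e-7
    contained[i] <- FALSE
    keep[i] <- !any(contained)
  }
  data.frame(x = fg[keep, 1], y = fg[keep, 2], radius = dv[keep])
}

## random blob masks: scattered disks, plus salt noise
randomMask <- function(w = 32, h = 32, ndisks = 4, salt = 0.02) {
  m <- matrix(0, w, h)
  for (k in seq_len(ndisks)) {
    cx <- runif(1, 1, w); cy <- runif(1, 1, h); r <- runif(1, 1, 6)
    m[outer((1:w - cx)^2, (1:h - cy)^2, "+") <= r^2] <- 1
  }
  m[matrix(runif(w * h) < salt, w, h)] <- 1
  m
}

diskMask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  m <- matrix(0, n, n)
  m[outer((1:n - cx)^2, (1:n - cy)^2, "+") <= r^2] <- 1
  m
}

## RGB image of three vertical uniform patches (8-bit colors)
threePatchImage <- function(colors, w = 60, h = 30) {
  a <- array(0, c(w, h, 3))
  cuts <- round(seq(0, w, length.out = 4))
  for (k in 1:3)
    a[(cuts[k] + 1):cuts[k + 1], , ] <-
      rep(colors[[k]], each = (cuts[k + 1] - cuts[k]) * h)
  EBImage::Image(a / 255, colormode = "Color")
}

grayPatchImage <- function(levels, w = 60, h = 30) {
  threePatchImage(lapply(levels, function(v) c(v, v, v)), w, h)
}

## scene spec sized for fast tests: 448 px tiles at the reference
## resolution, with accordingly smaller lumens
testSceneSpec <- function(..., seed = 0) {
  sceneSpec(width = 1344, height = 1344, rows = 3, cols = 3,
            lumenRangeNormal = c(4, 9), lumenRangeSingleLayer = c(5, 20),
            lobulesPerTile = 4, seed = seed, ...)
}

expectedLabel <- c(normal = "unaffected", pathological = "affected",
                   fat = "non_informative")
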