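test_that("preprocessing performs the stated shape arithmetic", {
  p <- defaultParameters(cropFraction = 0.8, downscaleFactor = 2L)
  out <- preprocessFrame(matrix(100, 500, 500), p)
  expect_equal(dim(out), c(200L, 200L))
  # constant frame: contrast stretch is the identity
  expect_true(all(out == 100))
})

test_that("block-mean downscale averages each block", {
  p <- defaultParameters(downscaleFactor = 2L)
  out <- preprocessFrame(matrix(c(10, 30, 20, 40), 2, 2), p)
  expect_equal(dim(out), c(1L, 1L))
  expect_equal(out[1, 1], 25)
})

test_that("degenerate crops and downscales are rejected", {
  p <- defaultParameters(downscaleFactor = 8L)
  expect_error(preprocessFrame(matrix(0, 4, 4), p), "empty")
})

test_that("five identical frames produce empty cell and artifact masks", {
  batch <- buildBatch(function(i) matrix(150, 60, 60))
  p <- plainParams()
  expect_false(any(cellMask(batch, p)))
  expect_false(any(artifactMask(batch, p)))
  expect_identical(cellCounts(countCells(batch, p)), rep(0L, 5))
})

test_that("a pixel block differing in one frame is positive only in that frame's mask", {
  # frame 3 carries a +12 block; the other four are identical, so the
  # deviation is 12 in frame 3 and 3 elsewhere: only frame 3 crosses a
  # threshold of 10
  batch <- buildBatch(function(i) {
    m <- matrix(100, 40, 40)
    if (i == 3) m[18:20, 18:20] <- 112
    m
  })
  p <- plainParams(cellBatchDiffThreshold = 10,
                   contrastLowPct = 0, contrastHighPct = 100)
  masks <- cellMask(batch, p)
  expect_true(all(masks[18:20, 18:20, 3]))
  for (i in c(1, 2, 4, 5)) expect_false(any(masks[, , i]))
})

test_that("a single moving cell yields one component per frame near its true position", {
  batch <- movingCellBatch(size = 200L, start = c(40, 100), dx = 30)
  p <- defaultParameters(downscaleFactor = 1L, cellMinArea = 2)
  det <- countCells(batch, p)
  expect_identical(cellCounts(det), rep(1L, 5))
  for (i in 1:5) {
    cc <- cellCentroids(det)[[i]]
    expect_lt(abs(cc[1, "x"] - (40 + (i - 1) * 30 - 1)), 3)
    expect_lt(abs(cc[1, "y"] - 99), 3)
  }
})

test_that("raising the batch difference threshold never adds positive pixels", {
  sim <- makeFrameBatch(smallScene(trueConcentration = 150, seed = 9L))
  pLow <- plainParams(cellBatchDiffThreshold = 30)
  pHigh <- plainParams(cellBatchDiffThreshold = 60)
  mLow <- cellMask(sim$batch, pLow)
  mHigh <- cellMask(sim$batch, pHigh)
  expect_lte(sum(mHigh), sum(mLow))
})

test_that("static structures shared by all five frames never enter the masks", {
  base <- movingCellBatch(size = 200L)
  withBlob <- base
  fr <- frames(withBlob)
  for (i in 1:5) {
    fr[60:80, 120:140, i] <- fr[60:80, 120:140, i] - 70  # stuck debris
  }
  withBlob@frames <- fr
  p <- defaultParameters(downscaleFactor = 1L, cellMinArea = 2)
  expect_identical(cellCounts(countCells(base, p)),
                   cellCounts(countCells(withBlob, p)))
  expect_false(any(cellMask(withBlob, p)[55:85, 115:145, ]))
})

test_that("a large moving bright object is masked and produces no cell counts", {
  size <- 200L
  bubble <- buildBatch(function(i) {
    m <- matrix(150, size, size)
    x <- 50 + (i - 1) * 20
    m[80:120, pmax(1, x - 20):pmin(size, x + 20)] <- 240
    m
  })
  p <- defaultParameters(downscaleFactor = 1L, artifactDownscaleFactor = 2L,
                         cellMaxArea = 400, artifactMinArea = 400)
  det <- countCells(bubble, p)
  expect_identical(cellCounts(det), rep(0L, 5))
  for (i in 1:5) {
    x <- 50 + (i - 1) * 20
    expect_true(all(det@artifactMasks[90:110, (x - 10):(x + 10), i]))
  }
})

test_that("an object below the artifact size floor is not artifact-masked", {
  size <- 120L
  small <- buildBatch(function(i) {
    m <- matrix(150, size, size)
    x <- 30 + (i - 1) * 15
    m[60:63, x:(x + 3)] <- 240   # 16 px^2, far below artifactMinArea
    m
  })
  p <- defaultParameters(downscaleFactor = 1L, artifactDownscaleFactor = 2L)
  expect_false(any(artifactMask(small, p)))
})

test_that("a cell whose centroid falls inside a bubble region is excluded", {
  size <- 200L
  mk <- function(withBubble) buildBatch(function(i) {
    m <- matrix(150, size, size)
    x <- 60 + (i - 1) * 20
    if (withBubble) m[60:140, pmax(1, x - 40):pmin(size, x + 40)] <- 240
    cx <- 60 + (i - 1) * 20   # cell rides inside the bubble's span
    for (r in 95:105) for (cc in pmax(1, cx - 5):pmin(size, cx + 5)) {
      m[r, cc] <- m[r, cc] - 80 * exp(-((cc - cx)^2 + (r - 100)^2) / 8)
    }
    m
  })
  p <- defaultParameters(downscaleFactor = 1L, cellMinArea = 2,
                         artifactDownscaleFactor = 2L,
                         cellMaxArea = 400, artifactMinArea = 2000)
  expect_identical(cellCounts(countCells(mk(TRUE), p)), rep(0L, 5))
  expect_identical(cellCounts(countCells(mk(FALSE), p)), rep(1L, 5))
})

test_that("counting is deterministic and bounded", {
  sim <- makeFrameBatch(smallScene(trueConcentration = 150, seed = 31L))
  p <- defaultParameters()
  d1 <- countCells(sim$batch, p)
  d2 <- countCells(sim$batch, p)
  expect_identical(cellCounts(d1), cellCounts(d2))
  expect_identical(cellCentroids(d1), cellCentroids(d2))
  bound <- prod(dim(d1@cellMasks)[1:2]) / p@cellMinArea
  expect_true(all(cellCounts(d1) >= 0 & cellCounts(d1) <= bound))
})

test_that("batches must contain exactly five frames", {
  a <- array(100, dim = c(20, 20, 4))
  expect_error(new("FrameBatch", frames = a), "5 frames")
  expect_error(cellMask(array(100, dim = c(20, 20, 4)),
                        plainParams()), "5 frames")
})
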