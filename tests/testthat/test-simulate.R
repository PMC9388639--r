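test_that("an empty noiseless scene yields five identical frames and zero truth", {
  cfg <- smallScene(trueConcentration = 0, nBubbles = 0L,
                    shotNoiseAmplitude = 0, seed = 5L)
  sim <- makeFrameBatch(cfg)
  fr <- frames(sim$batch)
  for (i in 2:5) expect_identical(fr[, , i], fr[, , 1])
  expect_identical(cellCounts(sim$truth), rep(0L, 5))
})

test_that("the same config and seed reproduce a batch bit for bit", {
  cfg <- smallScene(trueConcentration = 120, nBubbles = 1L, seed = 77L)
  a <- makeFrameBatch(cfg)
  b <- makeFrameBatch(cfg)
  expect_identical(frames(a$batch), frames(b$batch))
  expect_identical(cellCentroids(a$truth), cellCentroids(b$truth))
  expect_identical(a$truth@artifacts, b$truth@artifacts)
})

test_that("truth counts follow concentration x imaged volume, and scale linearly", {
  cfg <- smallScene(trueConcentration = 100, nBubbles = 0L)
  expectCells <- 100 * imagedVolume(cfg)   # 0.5 x 0.5 x 0.2 mm -> 5
  draws <- function(conc, seeds) {
    vapply(seeds, function(s) {
      cellCounts(makeFrameBatch(
        smallScene(trueConcentration = conc, nBubbles = 0L,
                   noiseAmplitude = 0, shotNoiseAmplitude = 0, seed = s)
      )$truth)[1]
    }, integer(1))
  }
  n1 <- draws(100, 1:200)
  se <- sqrt(expectCells / 200)
  expect_lt(abs(mean(n1) - expectCells), 3 * se)
  n2 <- draws(200, 201:400)
  expect_lt(abs(mean(n2) - 2 * expectCells), 3 * sqrt(2 * expectCells / 200))
})

test_that("truth centroids stay in bounds and match the per-frame counts", {
  for (s in 1:5) {
    cfg <- smallScene(trueConcentration = 150, seed = s)
    tr <- makeFrameBatch(cfg)$truth
    for (i in 1:5) {
      cc <- cellCentroids(tr)[[i]]
      expect_equal(nrow(cc), cellCounts(tr)[i])
      if (nrow(cc) > 0) {
        expect_true(all(cc[, "x"] >= 0 & cc[, "x"] < cfg@frameWidthPx))
        expect_true(all(cc[, "y"] >= 0 & cc[, "y"] < cfg@frameHeightPx))
      }
    }
  }
})

test_that("a drain is split into five-frame batches with a fixed batch size", {
  cfg <- smallScene(trueConcentration = 0, shotNoiseAmplitude = 0, seed = 1L)
  expect_length(makeDrainImages(cfg, 100L)$batches, 20L)
  expect_length(makeDrainImages(cfg, 5L)$batches, 1L)
  expect_error(makeDrainImages(cfg, 7L), "5")
})

test_that("invalid scene configurations are rejected", {
  expect_error(sceneConfig(frameWidthPx = 0), "positive")
  expect_error(sceneConfig(trueConcentration = -1), ">= 0")
  expect_error(sceneConfig(samplingDepth = 0), "> 0")
})

test_that("the count dataset matches the training design dimensions", {
  ds <- makeCountDataset(countDatasetConfig(seed = 3L))
  tab <- table(ds$concentration)
  expect_length(tab, 9L)
  expect_true(all(tab == 1800L))
  expect_true(all(ds$count >= 0))
  expect_true(all(ds$count == floor(ds$count)))
})

test_that("zero dispersion collapses counts onto the generating line", {
  ds <- makeCountDataset(countDatasetConfig(
    concentrations = 100, nSamples = 3L, nImages = 10L,
    trueSlope = 0.1, trueIntercept = 0, dispersion = 0, seed = 1L
  ))
  expect_true(all(ds$count == 10L))
})

test_that("count means follow the linear law at high concentration", {
  at300 <- unlist(lapply(11:13, function(s) {
    ds <- makeCountDataset(countDatasetConfig(
      trueSlope = 0.1, trueIntercept = 0, seed = s
    ))
    ds$count[ds$concentration == 300]
  }))
  se <- stats::sd(at300) / sqrt(length(at300))
  expect_lt(abs(mean(at300) - 30), 3 * se)
})

test_that("count variance grows with concentration under default dispersion", {
  ds <- makeCountDataset(countDatasetConfig(seed = 21L))
  v50 <- stats::var(ds$count[ds$concentration == 50])
  v300 <- stats::var(ds$count[ds$concentration == 300])
  expect_gt(v300, v50)
})

test_that("a negative generating mean is clamped to zero with a warning", {
  cfg <- countDatasetConfig(
    concentrations = c(0, 50), nSamples = 1L, nImages = 5L,
    trueSlope = 0.1, trueIntercept = -2, seed = 1L
  )
  expect_warning(ds <- makeCountDataset(cfg), "clamped")
  expect_true(all(ds$count[ds$concentration == 0] == 0L))
})
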