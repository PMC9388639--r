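test_that("the IQR filter keeps the middle half by rank", {
  expect_equal(iqrFilter(1:8), 3:6)
  expect_length(iqrFilter(rpois(100, 7)), 50L)
  expect_equal(iqrFilter(rep(7, 100)), rep(7, 50))
  expect_error(iqrFilter(1:3), "at least 4")
})

test_that("the IQR filter retains exactly floor(n/2) values, a multiset subset", {
  set.seed(42)
  for (n in c(4, 5, 7, 10, 99, 100, 101, 1800)) {
    v <- rpois(n, 12)
    kept <- iqrFilter(v)
    expect_length(kept, floor(n / 2))
    # multiset subset: every kept value occurs at most as often as in v
    tk <- table(kept)
    tv <- table(v)
    expect_true(all(tk <= tv[names(tk)]))
  }
})

test_that("OLS matches exact lines and the normal-equations oracle", {
  expect_equal(fitOLS(c(0, 10), c(0, 100)),
               c(slope = 10, intercept = 0))
  expect_equal(fitOLS(c(1, 2, 3), c(50, 50, 50)),
               c(slope = 0, intercept = 50))
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(20); y <- 3 * x + rnorm(20)
    expect_equal(fitOLS(x, y), olsOracle(x, y), tolerance = 1e-9)
  }
  expect_error(fitOLS(rep(2, 5), 1:5), "degenerate")
})

test_that("weighted R^2 matches its defining formula", {
  # perfect fit
  x <- rep(c(1, 2, 3), each = 5) + rep(seq(-0.2, 0.2, 0.1), 3)
  y <- 10 * x
  expect_equal(weightedR2(x, y, 10, 0), 1)
  # null model: predictions equal to the weighted mean give 0
  set.seed(1)
  counts <- rep(c(2, 5, 9), each = 10) + rnorm(30, 0, 0.5)
  conc <- rep(c(20, 50, 90), each = 10)
  # slope 0 falls back to uniform weights; intercept = plain mean
  expect_equal(weightedR2(counts, conc, 0, mean(conc)), 0)
  # heteroskedastic data vs an independent evaluation of the formula
  set.seed(2)
  conc2 <- rep(c(0, 50, 100, 200), each = 25)
  counts2 <- 0.1 * conc2 + rnorm(100, 0, 0.3 + 0.005 * conc2)
  slope <- 9.5; intercept <- 2
  groups <- factor(conc2)
  v <- tapply(counts2, groups, var)[groups] * slope^2
  w <- 1 / v
  yhat <- slope * counts2 + intercept
  ybw <- sum(w * conc2) / sum(w)
  expected <- 1 - sum(w * (conc2 - yhat)^2) / sum(w * (conc2 - ybw)^2)
  expect_equal(weightedR2(counts2, conc2, slope, intercept), expected,
               tolerance = 1e-12)
})

test_that("k-fold training splits 900 records into 90/810 folds", {
  set.seed(5)
  ds2 <- data.frame(
    concentration = rep(c(0, 100, 300), each = 300),
    count = c(rpois(300, 1), rpois(300, 20), rpois(300, 60))
  )
  m <- kfoldTrain(ds2, k = 10, seed = 2)
  expect_identical(m@k, 10L)
  expect_true(all(foldTable(m)$n_test == 90L))
})

test_that("a noiseless linear dataset gives identical folds with zero spread", {
  ds <- data.frame(
    concentration = rep(c(0, 50, 100, 200), each = 25),
    count = rep(c(0, 5, 10, 20), each = 25)
  )
  m <- kfoldTrain(ds, k = 10, seed = 3)
  expect_equal(modelSlope(m), 10, tolerance = 1e-9)
  expect_equal(modelIntercept(m), 0, tolerance = 1e-9)
  expect_lt(m@slopeSD, 1e-9)
  expect_lt(m@interceptSD, 1e-9)
})

test_that("k-fold training is reproducible and validates its inputs", {
  ds <- data.frame(
    concentration = rep(c(0, 100), each = 50),
    count = c(rpois(50, 1), rpois(50, 10))
  )
  m1 <- kfoldTrain(ds, k = 5, seed = 9)
  m2 <- kfoldTrain(ds, k = 5, seed = 9)
  expect_identical(foldTable(m1), foldTable(m2))
  expect_error(kfoldTrain(ds[1:4, ], k = 10), "at least")
  expect_error(kfoldTrain(data.frame(concentration = rep(1, 20),
                                     count = rpois(20, 5)), k = 5),
               "distinct")
})

test_that("cross-validated training recovers the generating calibration slope", {
  cfg <- countDatasetConfig(trueSlope = 0.1, trueIntercept = 0,
                            nSamples = 6L, seed = 13L)
  ds <- makeCountDataset(cfg)
  m <- kfoldTrain(iqrFilterDataset(ds), k = 10, seed = 13)
  # generating count law mu = 0.1 * C inverts to concentration = 10 * count
  expect_lt(abs(modelSlope(m) - 10) / 10, 0.05)
})

test_that("predictions apply the line and clamp at zero", {
  m <- list(slope = 1, intercept = 0)
  expect_equal(predictConcentration(10, m), 10)
  expect_equal(predictConcentration(2, list(slope = 10, intercept = -50)), 0)
  # non-decreasing in count for non-negative slope
  p <- predictConcentration(0:50, list(slope = 10, intercept = -50))
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0))
})

test_that("drain concentrations chain the filter, the line, and the mean", {
  m <- list(slope = 10, intercept = 0)
  out <- drainConcentration(1:8, m)
  expect_equal(out$concentrations, c(30, 40, 50, 60))
  expect_equal(out$mean, 45)
  same <- drainConcentration(rep(4L, 100), m)
  expect_equal(same$mean, 40)
})

test_that("a calibrated model recovers simulated drain concentrations", {
  ds <- makeCountDataset(countDatasetConfig(seed = 101L))
  model <- kfoldTrain(iqrFilterDataset(ds), k = 10, seed = 101)
  errs <- vapply(1:8, function(s) {
    drain <- makeDrainImages(
      sceneConfig(trueConcentration = 100, nBubbles = 0L, seed = 500L + s),
      nImages = 20L
    )
    counts <- unlist(lapply(drain$batches,
                            function(b) cellCounts(countCells(b))))
    drainConcentration(counts, model)$mean - 100
  }, numeric(1))
  expect_lt(mean(abs(errs)), 20)
})
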