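#' Describe a synthetic flowing-effluent scene
#'
#' Builds a [SceneConfig-class] with defaults emulating the in-line
#' imaging geometry: a ~1000 x 1000 um field of view at 2 um/pixel
#' (500 x 500 px frames) and an effective imaged depth of 0.2 mm, so a
#' concentration of 100 WBCs/mm^3 yields an expected 20 cells per frame.
#' Cells are dark Gaussian-profile disks of typical WBC size (8-15 um)
#' carried 40 px per 100 ms by the flow; bubbles are much larger bright
#' annuli carried by the same flow. The static background carries
#' fixed-pattern noise shared by all five frames; shot noise is drawn
#' independently per frame.
#'
#' @param frameWidthPx,frameHeightPx frame size in pixels.
#' @param pixelPitch micrometres per pixel.
#' @param trueConcentration WBCs per mm^3 (>= 0).
#' @param samplingDepth imaged optical depth in mm.
#' @param cellDiameterRange cell diameter range, um.
#' @param cellIntensityDelta grayscale offset of a cell centre vs
#'   background (negative = darker).
#' @param flowDisplacementPx inter-frame displacement, px per 100 ms.
#' @param noiseAmplitude sd of static fixed-pattern noise (grayscale).
#' @param shotNoiseAmplitude sd of per-frame independent noise.
#' @param nBubbles number of bubble artifacts.
#' @param bubbleDiameterRange bubble diameter range, um.
#' @param seed integer seed.
#' @return a validated [SceneConfig-class].
#' @examples
#' cfg <- sceneConfig(trueConcentration = 100, seed = 7)
#' sim <- makeFrameBatch(cfg)
#' cellCounts(sim$truth)
#' @export
sceneConfig <- function(frameWidthPx = 500L, frameHeightPx = 500L,
                        pixelPitch = 2, trueConcentration = 100,
                        samplingDepth = 0.2,
                        cellDiameterRange = c(8, 15),
                        cellIntensityDelta = -60,
                        flowDisplacementPx = 40,
                        noiseAmplitude = 6, shotNoiseAmplitude = 2,
                        nBubbles = 0L,
                        bubbleDiameterRange = c(100, 300),
                        seed = 1L) {
  new("SceneConfig",
    frameWidthPx = as.integer(frameWidthPx),
    frameHeightPx = as.integer(frameHeightPx),
    pixelPitch = as.numeric(pixelPitch),
    trueConcentration = as.numeric(trueConcentration),
    samplingDepth = as.numeric(samplingDepth),
    cellDiameterRange = as.numeric(cellDiameterRange),
    cellIntensityDelta = as.numeric(cellIntensityDelta),
    flowDisplacementPx = as.numeric(flowDisplacementPx),
    noiseAmplitude = as.numeric(noiseAmplitude),
    shotNoiseAmplitude = as.numeric(shotNoiseAmplitude),
    nBubbles = as.integer(nBubbles),
    bubbleDiameterRange = as.numeric(bubbleDiameterRange),
    seed = as.integer(seed)
  )
}

#' Imaged volume of one frame
#'
#' @param config a [SceneConfig-class].
#' @return volume in mm^3:
#'   \code{(width*pitch) * (height*pitch) * depth / 1e6}.
#' @export
imagedVolume <- function(config) {
  wmm <- config@frameWidthPx * config@pixelPitch / 1000
  hmm <- config@frameHeightPx * config@pixelPitch / 1000
  wmm * hmm * config@samplingDepth
}

## Additive render of a Gaussian-profile disk into `img` (by reference
## semantics via return). Centre (x, y) 0-based, sigma in px.
renderDisk <- function(img, x, y, sigma, delta, extent = 3) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(extent * sigma)
  if (x + r < 0 || x - r > w - 1 || y + r < 0 || y - r > h - 1) {
    return(img)  # entirely outside the field
  }
  cols <- max(0, floor(x - r)):min(w - 1, ceiling(x + r))
  rows <- max(0, floor(y - r)):min(h - 1, ceiling(y + r))
  dx <- outer(rep(1, length(rows)), cols - x)
  dy <- outer(rows - y, rep(1, length(cols)))
  prof <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
  img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + delta * prof
  img
}

## Additive render of a bright bubble: a Gaussian ring of radius R plus a
## faint brightened interior (thin-shell refraction look).
renderBubble <- function(img, x, y, R) {
  h <- nrow(img); w <- ncol(img)
  ringSigma <- max(1.5, R / 8)
  r <- ceiling(R + 3 * ringSigma)
  if (x + r < 0 || x - r > w - 1 || y + r < 0 || y - r > h - 1) {
    return(img)  # entirely outside the field
  }
  cols <- max(0, floor(x - r)):min(w - 1, ceiling(x + r))
  rows <- max(0, floor(y - r)):min(h - 1, ceiling(y + r))
  dx <- outer(rep(1, length(rows)), cols - x)
  dy <- outer(rows - y, rep(1, length(cols)))
  dist <- sqrt(dx^2 + dy^2)
  ring <- 55 * exp(-((dist - R)^2) / (2 * ringSigma^2))
  interior <- 18 * (dist < R)
  img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + ring + interior
  img
}

#' Simulate one five-frame capture burst with ground truth
#'
#' Draws a Poisson number of cells (mean = concentration x imaged volume),
#' places them uniformly, and advances every suspended object by
#' \code{flowDisplacementPx} along x between consecutive frames with
#' wrap-around (an object leaving one edge re-enters at the opposite edge,
#' standing in for new entrants so the expected density stays constant
#' within the batch). The background (base level plus fixed-pattern
#' noise) is identical across the five frames; only shot noise differs.
#' Frames are quantised to 8-bit integers.
#'
#' @param config a [SceneConfig-class]; its \code{seed} drives all
#'   randomness, so the same config reproduces the batch bit for bit.
#' @return list with elements \code{batch} ([FrameBatch-class]) and
#'   \code{truth} ([SceneTruth-class]).
#' @examples
#' sim <- makeFrameBatch(sceneConfig(trueConcentration = 50, seed = 3))
#' sim$batch
#' @export
makeFrameBatch <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  h <- config@frameHeightPx
  w <- config@frameWidthPx
  set.seed(config@seed)

  bgLevel <- 180
  background <- matrix(bgLevel, h, w)
  if (config@noiseAmplitude > 0) {
    background <- background +
      matrix(stats::rnorm(h * w, 0, config@noiseAmplitude), h, w)
  }

  nCells <- stats::rpois(1, config@trueConcentration * imagedVolume(config))
  cellX <- stats::runif(nCells, 0, w)
  cellY <- stats::runif(nCells, 0, h)
  cellDiamPx <- stats::runif(
    nCells, config@cellDiameterRange[1], config@cellDiameterRange[2]
  ) / config@pixelPitch

  nb <- config@nBubbles
  bubX <- stats::runif(nb, 0, w)
  bubY <- stats::runif(nb, 0, h)
  bubRPx <- stats::runif(
    nb, config@bubbleDiameterRange[1], config@bubbleDiameterRange[2]
  ) / (2 * config@pixelPitch)

  framesArr <- array(0, dim = c(h, w, 5))
  centroids <- vector("list", 5)
  artifacts <- vector("list", 5)
  counts <- integer(5)

  for (i in 1:5) {
    shift <- (i - 1) * config@flowDisplacementPx
    img <- background
    cx <- (cellX + shift) %% w
    cy <- cellY
    if (nCells > 0) {
      for (j in seq_len(nCells)) {
        img <- renderDisk(
          img, cx[j], cy[j],
          sigma = cellDiamPx[j] / 4, delta = config@cellIntensityDelta
        )
      }
    }
    # bubbles are carried out of the field rather than wrapped: a bubble
    # that leaves is gone, unlike the cell population whose density is
    # held constant by re-entry
    bx <- bubX + shift
    if (nb > 0) {
      for (j in seq_len(nb)) {
        img <- renderBubble(img, bx[j], bubY[j], bubRPx[j])
      }
    }
    if (config@shotNoiseAmplitude > 0) {
      img <- img +
        matrix(stats::rnorm(h * w, 0, config@shotNoiseAmplitude), h, w)
    }
    framesArr[, , i] <- round(pmin(255, pmax(0, img)))
    centroids[[i]] <- cbind(x = cx, y = cy)
    counts[i] <- nCells
    artifacts[[i]] <- data.frame(
      x = bx, y = bubY[seq_len(nb)], r = bubRPx[seq_len(nb)]
    )
  }

  batch <- new("FrameBatch", frames = framesArr, spacingMs = 100)
  truth <- new("SceneTruth",
    centroids = centroids, counts = counts, artifacts = artifacts,
    trueConcentration = config@trueConcentration
  )
  list(batch = batch, truth = truth)
}

#' Simulate all capture bursts of one drain
#'
#' One drain is imaged as \code{nImages} frames in bursts of five
#' (nominally 100 frames = 20 batches); the concentration is constant
#' within a drain. Per-batch seeds are derived from \code{config@seed}
#' so the whole drain is reproducible.
#'
#' @param config a [SceneConfig-class].
#' @param nImages number of frames; must be divisible by 5.
#' @return list with \code{batches} (list of [FrameBatch-class]) and
#'   \code{truths} (list of [SceneTruth-class]).
#' @export
makeDrainImages <- function(config, nImages = 100L) {
  stopifnot(is(config, "SceneConfig"))
  nImages <- as.integer(nImages)
  if (nImages < 5L || nImages %% 5L != 0L) {
    stop("nImages must be a positive multiple of the batch size (5)")
  }
  nBatches <- nImages %/% 5L
  set.seed(config@seed)
  batchSeeds <- sample.int(.Machine$integer.max - 1L, nBatches)
  out <- lapply(batchSeeds, function(s) {
    cfg <- config
    cfg@seed <- s
    makeFrameBatch(cfg)
  })
  list(
    batches = lapply(out, `[[`, "batch"),
    truths = lapply(out, `[[`, "truth")
  )
}

#' Configuration of the synthetic count-vs-concentration dataset
#'
#' Mirrors the calibration training design: a panel of spiked
#' concentrations, a number of patient samples per concentration, and
#' 100 images per sample. Counts are drawn from a negative-binomial
#' family whose mean follows the linear count law
#' \code{mu = trueSlope * C + trueIntercept} and whose variance
#' \code{mu * (1 + dispersion * C)} grows with concentration
#' (heteroskedastic). \code{dispersion = 0} is the degenerate
#' deterministic case: every count equals \code{round(mu)}.
#'
#' The default \code{trueSlope} of 0.2 counts per (WBC/mm^3) matches the
#' scene simulator's yield at its default 0.2 mm imaged depth, so a
#' calibration trained on this dataset applies to simulated drains.
#'
#' @param concentrations spiked WBC concentrations, WBCs/mm^3.
#' @param nSamples patient samples per concentration.
#' @param nImages images per sample.
#' @param trueSlope,trueIntercept generating linear count law
#'   (mean count per image as a function of concentration).
#' @param dispersion heteroskedasticity control (>= 0).
#' @param seed integer seed.
#' @return a list of class \code{countDatasetConfig}.
#' @export
countDatasetConfig <- function(concentrations = c(0, 50, 80, 100, 120,
                                                  150, 200, 250, 300),
                               nSamples = 18L, nImages = 100L,
                               trueSlope = 0.2, trueIntercept = 0.2,
                               dispersion = 0.002, seed = 1L) {
  stopifnot(
    length(concentrations) >= 1, all(concentrations >= 0),
    nSamples >= 1, nImages >= 1, dispersion >= 0
  )
  structure(
    list(
      concentrations = as.numeric(concentrations),
      nSamples = as.integer(nSamples),
      nImages = as.integer(nImages),
      trueSlope = as.numeric(trueSlope),
      trueIntercept = as.numeric(trueIntercept),
      dispersion = as.numeric(dispersion),
      seed = as.integer(seed)
    ),
    class = "countDatasetConfig"
  )
}

#' Generate a synthetic count dataset
#'
#' For each concentration C the generator emits
#' \code{nSamples * nImages} non-negative integer counts with mean
#' \code{trueSlope * C + trueIntercept} and variance
#' \code{mu * (1 + dispersion * C)}, labelled by concentration and
#' sample id. A negative generating mean is clamped to zero with a
#' warning.
#'
#' @param config a [countDatasetConfig()].
#' @return data.frame with columns \code{concentration, sample_id,
#'   image_index, count}.
#' @examples
#' ds <- makeCountDataset(countDatasetConfig(nSamples = 2, nImages = 10))
#' table(ds$concentration)
#' @export
makeCountDataset <- function(config) {
  stopifnot(inherits(config, "countDatasetConfig"))
  set.seed(config$seed)
  rows <- lapply(config$concentrations, function(C) {
    mu <- config$trueSlope * C + config$trueIntercept
    if (mu < 0) {
      warning("generating mean below zero at concentration ", C,
              "; clamped to 0")
      mu <- 0
    }
    n <- config$nSamples * config$nImages
    counts <- if (mu == 0) {
      rep(0L, n)
    } else if (config$dispersion == 0) {
      rep(as.integer(round(mu)), n)
    } else if (config$dispersion * C == 0) {
      stats::rpois(n, mu)
    } else {
      # var = mu * (1 + dispersion * C)  =>  size = mu / (dispersion * C)
      stats::rnbinom(n, mu = mu, size = mu / (config$dispersion * C))
    }
    data.frame(
      concentration = C,
      sample_id = rep(seq_len(config$nSamples), each = config$nImages),
      image_index = rep(seq_len(config$nImages), config$nSamples),
      count = as.integer(counts)
    )
  })
  do.call(rbind, rows)
}
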