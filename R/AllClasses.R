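#' @import methods
NULL

#' FrameBatch: one five-image capture burst
#'
#' Container for the unit of analysis of the in-line imaging pipeline:
#' five co-registered 8-bit grayscale frames captured 100 ms apart while
#' effluent flows through the viewing chamber. Frames are stored as a
#' numeric \code{height x width x 5} array with intensities in
#' \code{[0, 255]}; \code{frame[i, j]} is row \code{i} (y), column
#' \code{j} (x).
#'
#' @slot frames numeric array, \code{dim = c(height, width, 5)}.
#' @slot spacingMs numeric(1), nominal inter-frame spacing in ms
#'   (metadata only; the pipeline is timing-agnostic).
#'
#' @seealso [makeFrameBatch()], [countCells()]
#' @export
setClass("FrameBatch",
  representation(frames = "array", spacingMs = "numeric"),
  prototype(spacingMs = 100)
)

setValidity("FrameBatch", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3-d array")
  if (d[3] != 5L) return("a batch must contain exactly 5 frames")
  if (d[1] < 1L || d[2] < 1L) return("frames must be non-empty")
  rng <- range(object@frames)
  if (!all(is.finite(rng))) return("frame intensities must be finite")
  if (rng[1] < 0 || rng[2] > 255) {
    return("intensities must lie within 8-bit range [0, 255]")
  }
  if (length(object@spacingMs) != 1L || object@spacingMs <= 0) {
    return("spacingMs must be a positive scalar")
  }
  TRUE
})

#' ParameterSet: tunable knobs of the image batch analysis
#'
#' All parameters of preprocessing, cell masking, and bubble/artifact
#' masking. Lengths/areas are in pixels at the working resolution (after
#' crop and downscale), intensities in 8-bit grayscale units.
#'
#' @slot cropFraction fraction of each frame dimension retained centrally,
#'   in (0, 1]. The crop exists to remove out-of-focus border regions on
#'   real optics; the synthetic scenes are sharp to the edge, so the
#'   shipped default is 1.
#' @slot downscaleFactor integer >= 1, block-mean downscale factor.
#' @slot contrastLowPct,contrastHighPct percentile clip points (0-100)
#'   of the linear contrast stretch.
#' @slot cellBatchDiffThreshold grayscale cutoff on the absolute deviation
#'   of a pixel from the pooled mean of the other four frames.
#' @slot cellBlurSigma Gaussian blur sigma (px) applied to the raw cell
#'   mask to merge the turbulence trail around each cell.
#' @slot cellMinArea,cellMaxArea component area bounds (px^2) for cells.
#' @slot artifactDownscaleFactor additional integer downscale applied
#'   before artifact differencing.
#' @slot artifactBatchDiffThreshold grayscale cutoff of the artifact pass.
#' @slot artifactMinArea minimum component area (px^2, working scale)
#'   for a region to count as a bubble/artifact.
#' @slot artifactDilation dilation radius (px, working scale) applied to
#'   accepted artifact components.
#'
#' @seealso [defaultParameters()], [countCells()], [gridSearch()]
#' @export
setClass("ParameterSet",
  representation(
    cropFraction = "numeric",
    downscaleFactor = "integer",
    contrastLowPct = "numeric",
    contrastHighPct = "numeric",
    cellBatchDiffThreshold = "numeric",
    cellBlurSigma = "numeric",
    cellMinArea = "numeric",
    cellMaxArea = "numeric",
    artifactDownscaleFactor = "integer",
    artifactBatchDiffThreshold = "numeric",
    artifactMinArea = "numeric",
    artifactDilation = "numeric"
  )
)

setValidity("ParameterSet", function(object) {
  p <- object
  if (p@cropFraction <= 0 || p@cropFraction > 1) {
    return("cropFraction must be in (0, 1]")
  }
  if (p@downscaleFactor < 1L) return("downscaleFactor must be >= 1")
  if (p@artifactDownscaleFactor < 1L) {
    return("artifactDownscaleFactor must be >= 1")
  }
  if (p@contrastLowPct < 0 || p@contrastHighPct > 100 ||
      p@contrastLowPct >= p@contrastHighPct) {
    return("contrast percentiles must satisfy 0 <= low < high <= 100")
  }
  if (p@cellBatchDiffThreshold < 0 || p@artifactBatchDiffThreshold < 0) {
    return("difference thresholds must be >= 0")
  }
  if (p@cellBlurSigma < 0) return("cellBlurSigma must be >= 0")
  if (!(p@cellMinArea < p@cellMaxArea)) {
    return("cellMinArea must be < cellMaxArea")
  }
  if (!(p@cellMaxArea <= p@artifactMinArea)) {
    return("cellMaxArea must be <= artifactMinArea")
  }
  if (p@artifactDilation < 0) return("artifactDilation must be >= 0")
  TRUE
})

#' SceneConfig: synthetic flowing-effluent scene description
#'
#' Parameters of the scene simulator. Geometry is defined by the frame
#' size in pixels and the pixel pitch in micrometres; the imaged volume
#' per frame is \code{(width*pitch) x (height*pitch) x samplingDepth}
#' (converted to mm^3) and the expected number of cells per frame is
#' \code{trueConcentration} times that volume.
#'
#' @slot frameWidthPx,frameHeightPx positive integers, frame size.
#' @slot pixelPitch micrometres per pixel.
#' @slot trueConcentration WBCs per mm^3, >= 0.
#' @slot samplingDepth effective optical depth (mm) defining the imaged
#'   volume.
#' @slot cellDiameterRange numeric(2), cell diameter range in um.
#' @slot cellIntensityDelta signed grayscale offset of a cell centre
#'   relative to background (negative = darker).
#' @slot flowDisplacementPx per-100 ms inter-frame displacement of all
#'   suspended objects, in pixels along +x.
#' @slot noiseAmplitude sd (grayscale) of the static fixed-pattern noise
#'   shared by all five frames.
#' @slot shotNoiseAmplitude sd (grayscale) of per-frame independent noise.
#' @slot nBubbles integer >= 0, number of large moving bubble artifacts.
#' @slot bubbleDiameterRange numeric(2), bubble diameter range in um.
#' @slot seed integer seed; all randomness of a batch flows from it.
#'
#' @seealso [sceneConfig()], [makeFrameBatch()]
#' @export
setClass("SceneConfig",
  representation(
    frameWidthPx = "integer",
    frameHeightPx = "integer",
    pixelPitch = "numeric",
    trueConcentration = "numeric",
    samplingDepth = "numeric",
    cellDiameterRange = "numeric",
    cellIntensityDelta = "numeric",
    flowDisplacementPx = "numeric",
    noiseAmplitude = "numeric",
    shotNoiseAmplitude = "numeric",
    nBubbles = "integer",
    bubbleDiameterRange = "numeric",
    seed = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  if (object@frameWidthPx < 1L || object@frameHeightPx < 1L) {
    return("frame dimensions must be positive")
  }
  if (object@pixelPitch <= 0) return("pixelPitch must be > 0")
  if (object@trueConcentration < 0) {
    return("trueConcentration must be >= 0")
  }
  if (object@samplingDepth <= 0) return("samplingDepth must be > 0")
  if (length(object@cellDiameterRange) != 2L ||
      any(object@cellDiameterRange <= 0) ||
      diff(object@cellDiameterRange) < 0) {
    return("cellDiameterRange must be an increasing positive pair")
  }
  if (length(object@bubbleDiameterRange) != 2L ||
      any(object@bubbleDiameterRange <= 0) ||
      diff(object@bubbleDiameterRange) < 0) {
    return("bubbleDiameterRange must be an increasing positive pair")
  }
  if (object@noiseAmplitude < 0 || object@shotNoiseAmplitude < 0) {
    return("noise amplitudes must be >= 0")
  }
  if (object@nBubbles < 0L) return("nBubbles must be >= 0")
  TRUE
})

#' SceneTruth: simulator ground truth for one batch
#'
#' @slot centroids list of 5 two-column matrices (x, y), 0-based pixel
#'   coordinates of every cell centre in each frame.
#' @slot counts integer(5), true cell count per frame (the number of
#'   centroids in that frame).
#' @slot artifacts list of 5 data.frames with columns \code{x, y, r}
#'   (bubble centres and radii, px).
#' @slot trueConcentration echo of the generating concentration.
#' @export
setClass("SceneTruth",
  representation(
    centroids = "list",
    counts = "integer",
    artifacts = "list",
    trueConcentration = "numeric"
  )
)

setValidity("SceneTruth", function(object) {
  if (length(object@centroids) != 5L || length(object@counts) != 5L ||
      length(object@artifacts) != 5L) {
    return("truth must describe exactly 5 frames")
  }
  for (i in seq_len(5L)) {
    if (nrow(object@centroids[[i]]) != object@counts[i]) {
      return("per-frame count must equal the number of centroids")
    }
  }
  TRUE
})

#' FrameDetections: output of the image batch analysis
#'
#' @slot cellMasks logical array (h x w x 5) at working resolution.
#' @slot artifactMasks logical array (h x w x 5) at working resolution.
#' @slot centroids list of 5 two-column matrices (x, y), 0-based working
#'   resolution coordinates of retained cell components.
#' @slot counts integer(5), retained cells per frame.
#' @export
setClass("FrameDetections",
  representation(
    cellMasks = "array",
    artifactMasks = "array",
    centroids = "list",
    counts = "integer"
  )
)

setValidity("FrameDetections", function(object) {
  if (length(object@counts) != 5L || length(object@centroids) != 5L) {
    return("detections must cover exactly 5 frames")
  }
  for (i in seq_len(5L)) {
    if (nrow(object@centroids[[i]]) != object@counts[i]) {
      return("count must equal the number of centroids")
    }
  }
  if (any(object@counts < 0L)) return("counts must be >= 0")
  TRUE
})

#' CalibrationModel: linear count-to-concentration map
#'
#' Fold-averaged ordinary least squares calibration mapping a per-image
#' cell count to a WBC concentration (WBCs/mm^3), with cross-validation
#' diagnostics.
#'
#' @slot slope (WBCs/mm^3) per count.
#' @slot intercept WBCs/mm^3.
#' @slot weightedR2 fold-averaged heteroskedasticity-weighted R^2.
#' @slot slopeSD,interceptSD,r2SD dispersion of the per-fold estimates.
#' @slot k number of folds.
#' @slot foldTable data.frame, one row per fold (slope, intercept,
#'   weighted_r2, test RMSE).
#' @slot seed integer seed used to shuffle records into folds.
#' @export
setClass("CalibrationModel",
  representation(
    slope = "numeric",
    intercept = "numeric",
    weightedR2 = "numeric",
    slopeSD = "numeric",
    interceptSD = "numeric",
    r2SD = "numeric",
    k = "integer",
    foldTable = "data.frame",
    seed = "integer"
  )
)

setValidity("CalibrationModel", function(object) {
  if (object@k < 2L) return("k must be >= 2")
  if (is.finite(object@weightedR2) && object@weightedR2 > 1 + 1e-12) {
    return("weightedR2 must be <= 1")
  }
  TRUE
})

#' SessionReport: end-of-session screening summary
#'
#' @slot drainMeans per-drain mean WBC concentrations (WBCs/mm^3).
#' @slot sessionMean,sessionMin,sessionMax summary over drains.
#' @slot zone one of \code{"healthy"}, \code{"caution"}, \code{"risk"}.
#' @slot recommendation patient-facing follow-up text for the zone.
#' @export
setClass("SessionReport",
  representation(
    drainMeans = "numeric",
    sessionMean = "numeric",
    sessionMin = "numeric",
    sessionMax = "numeric",
    zone = "character",
    recommendation = "character"
  )
)

setValidity("SessionReport", function(object) {
  if (!(object@sessionMin <= object@sessionMean + 1e-9 &&
        object@sessionMean <= object@sessionMax + 1e-9)) {
    return("session min <= mean <= max must hold")
  }
  if (!object@zone %in% c("healthy", "caution", "risk")) {
    return("zone must be healthy, caution, or risk")
  }
  TRUE
})

#' ScreeningEvaluation: binary screening performance
#'
#' @slot tp,fp,tn,fn confusion counts at the chosen threshold.
#' @slot accuracy,sensitivity,specificity fractions; sensitivity and
#'   specificity are \code{NA} when their denominator is zero.
#' @slot auroc area under the ROC curve (NA if only one class present).
#' @slot threshold WBCs/mm^3 cutoff used for the confusion matrix.
#' @export
setClass("ScreeningEvaluation",
  representation(
    tp = "integer", fp = "integer", tn = "integer", fn = "integer",
    accuracy = "numeric", sensitivity = "numeric",
    specificity = "numeric", auroc = "numeric", threshold = "numeric"
  )
)

setValidity("ScreeningEvaluation", function(object) {
  tot <- object@tp + object@fp + object@tn + object@fn
  if (tot < 1L) return("evaluation must cover at least one sample")
  if (abs(object@accuracy - (object@tp + object@tn) / tot) > 1e-12) {
    return("accuracy must equal (TP + TN) / total")
  }
  TRUE
})

#' TuningResult: grid-search outcome
#'
#' @slot table data.frame with one row per parameter combination:
#'   the candidate values, Wilcoxon signed-rank statistic and p-value,
#'   Pearson r, and mean absolute count error against the reference.
#' @slot selected the winning [ParameterSet-class].
#' @export
setClass("TuningResult",
  representation(table = "data.frame", selected = "ParameterSet")
)
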