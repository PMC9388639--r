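#' @rdname FrameBatch-class
#' @export
setMethod("frames", "FrameBatch", function(object) object@frames)

#' @rdname FrameDetections-class
#' @export
setMethod("cellCounts", "FrameDetections", function(object) object@counts)

#' @rdname SceneTruth-class
#' @aliases cellCounts,SceneTruth-method
#' @param object a package object
#' @export
setMethod("cellCounts", "SceneTruth", function(object) object@counts)

#' @rdname FrameDetections-class
#' @export
setMethod("cellCentroids", "FrameDetections", function(object) {
  object@centroids
})

#' @rdname SceneTruth-class
#' @export
setMethod("cellCentroids", "SceneTruth", function(object) {
  object@centroids
})

#' @rdname CalibrationModel-class
#' @export
setMethod("modelSlope", "CalibrationModel", function(object) object@slope)

#' @rdname CalibrationModel-class
#' @export
setMethod("modelIntercept", "CalibrationModel", function(object) {
  object@intercept
})

#' @rdname CalibrationModel-class
#' @export
setMethod("weightedR2Value", "CalibrationModel", function(object) {
  object@weightedR2
})

#' @rdname CalibrationModel-class
#' @export
setMethod("foldTable", "CalibrationModel", function(object) {
  object@foldTable
})

#' @rdname SessionReport-class
#' @export
setMethod("sessionZone", "SessionReport", function(object) object@zone)

#' @rdname TuningResult-class
#' @export
setMethod("selectedParameters", "TuningResult", function(object) {
  object@selected
})

#' @rdname TuningResult-class
#' @export
setMethod("tuningTable", "TuningResult", function(object) object@table)

setMethod("show", "FrameBatch", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "FrameBatch: 5 frames of %d x %d px (8-bit), %g ms spacing\n",
    d[1], d[2], object@spacingMs
  ))
})

setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet (image batch analysis)\n")
  cat(sprintf(
    "  preprocess: crop %.2f, downscale %d, contrast %.1f-%.1f pct\n",
    object@cropFraction, object@downscaleFactor,
    object@contrastLowPct, object@contrastHighPct
  ))
  cat(sprintf(
    "  cell mask:  diff > %g, blur sigma %g, area [%g, %g] px^2\n",
    object@cellBatchDiffThreshold, object@cellBlurSigma,
    object@cellMinArea, object@cellMaxArea
  ))
  cat(sprintf(
    "  artifacts:  downscale %d, diff > %g, area >= %g px^2, dilate %g px\n",
    object@artifactDownscaleFactor, object@artifactBatchDiffThreshold,
    object@artifactMinArea, object@artifactDilation
  ))
})

setMethod("show", "FrameDetections", function(object) {
  cat(sprintf(
    "FrameDetections: per-frame counts %s\n",
    paste(object@counts, collapse = ", ")
  ))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf(
    "SceneTruth: %g WBCs/mm^3, per-frame counts %s\n",
    object@trueConcentration, paste(object@counts, collapse = ", ")
  ))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf(
    paste0(
      "CalibrationModel (k = %d folds, seed %d)\n",
      "  concentration = %.4f * count + %.4f   [WBCs/mm^3]\n",
      "  weighted R^2 = %.4f (sd %.2g); slope sd %.2g, intercept sd %.2g\n"
    ),
    object@k, object@seed, object@slope, object@intercept,
    object@weightedR2, object@r2SD, object@slopeSD, object@interceptSD
  ))
})

setMethod("show", "SessionReport", function(object) {
  cat(formatSessionReport(object))
})

setMethod("show", "ScreeningEvaluation", function(object) {
  cat(sprintf(
    paste0(
      "ScreeningEvaluation @ %g WBCs/mm^3\n",
      "  TP %d  FP %d  TN %d  FN %d\n",
      "  accuracy %.3f, sensitivity %s, specificity %s, AUROC %s\n"
    ),
    object@threshold, object@tp, object@fp, object@tn, object@fn,
    object@accuracy, format(object@sensitivity, digits = 3),
    format(object@specificity, digits = 3),
    format(object@auroc, digits = 3)
  ))
})

setMethod("show", "TuningResult", function(object) {
  cat(sprintf(
    "TuningResult: %d parameter combinations evaluated\n",
    nrow(object@table)
  ))
  cat("Selected:\n")
  show(object@selected)
})
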