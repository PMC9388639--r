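#' @rdname FrameBatch-class
#' @param object a package object
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname FrameDetections-class
#' @param object a package object
#' @export
setGeneric("cellCounts", function(object) standardGeneric("cellCounts"))

#' @rdname FrameDetections-class
#' @export
setGeneric("cellCentroids", function(object) {
  standardGeneric("cellCentroids")
})

#' @rdname CalibrationModel-class
#' @export
setGeneric("modelSlope", function(object) standardGeneric("modelSlope"))

#' @rdname CalibrationModel-class
#' @export
setGeneric("modelIntercept", function(object) {
  standardGeneric("modelIntercept")
})

#' @rdname CalibrationModel-class
#' @export
setGeneric("weightedR2Value", function(object) {
  standardGeneric("weightedR2Value")
})

#' @rdname CalibrationModel-class
#' @export
setGeneric("foldTable", function(object) standardGeneric("foldTable"))

#' @rdname SessionReport-class
#' @export
setGeneric("sessionZone", function(object) standardGeneric("sessionZone"))

#' @rdname TuningResult-class
#' @export
setGeneric("selectedParameters", function(object) {
  standardGeneric("selectedParameters")
})

#' @rdname TuningResult-class
#' @export
setGeneric("tuningTable", function(object) standardGeneric("tuningTable"))
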