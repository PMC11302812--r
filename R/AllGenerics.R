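#' @rdname magnification
#' @export
setGeneric("magnification", function(object) standardGeneric("magnification"))

#' @rdname pixels
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))

#' @rdname pixels
#' @export
setGeneric("motionAxis", function(object) standardGeneric("motionAxis"))

#' @rdname pixels
#' @export
setGeneric("axisPositions", function(object) standardGeneric("axisPositions"))

#' @rdname centerMm
#' @export
setGeneric("centerMm", function(object) standardGeneric("centerMm"))

#' @rdname centerMm
#' @export
setGeneric("centerPx", function(object) standardGeneric("centerPx"))

#' @rdname centerMm
#' @export
setGeneric("quality", function(object) standardGeneric("quality"))

#' @rdname delayMs
#' @export
setGeneric("delayMs", function(object) standardGeneric("delayMs"))

#' @rdname delayMs
#' @export
setGeneric("deltaX", function(object) standardGeneric("deltaX"))

#' @rdname delayMs
#' @export
setGeneric("phase", function(object) standardGeneric("phase"))

#' @rdname delayMs
#' @export
setGeneric("beamMode", function(object) standardGeneric("beamMode"))
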