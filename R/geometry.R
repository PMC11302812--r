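#' Construct a beam projection geometry
#'
#' @param sad source-to-axis distance in mm (default 1000).
#' @param sid source-to-imager distance in mm (default 1600).
#' @param pixelPitch detector pixel pitch in mm (default 0.34).
#' @param imageShape image size as (rows, cols) (default 256 x 256).
#'
#' @return A [BeamGeometry-class] object.
#' @examples
#' geom <- BeamGeometry()
#' magnification(geom)  # 1.6
#' @export
BeamGeometry <- function(sad = 1000, sid = 1600, pixelPitch = 0.34,
                         imageShape = c(256L, 256L)) {
  new("BeamGeometry", sad = as.numeric(sad), sid = as.numeric(sid),
      pixelPitch = as.numeric(pixelPitch),
      imageShape = as.integer(imageShape))
}

#' Projective magnification SID/SAD
#'
#' @param object a [BeamGeometry-class].
#' @return The dimensionless magnification (>= 1) mapping isocenter-plane
#'   millimetres onto detector-plane millimetres.
#' @rdname magnification
#' @export
setMethod("magnification", "BeamGeometry", function(object) {
  object@sid / object@sad
})

#' Construct a portal image
#'
#' @param pixels numeric matrix of detector counts.
#' @param pixelPitch mm per pixel (default 0.34).
#' @param motionAxis `"cols"` (default) or `"rows"`; the image axis along
#'   which the phantom moves.
#' @return A [PortalImage-class].
#' @export
PortalImage <- function(pixels, pixelPitch = 0.34, motionAxis = "cols") {
  new("PortalImage", pixels = pixels, pixelPitch = as.numeric(pixelPitch),
      motionAxis = motionAxis)
}

#' Portal image accessors
#'
#' `pixels()` returns the count matrix, `pixelPitch()` the mm-per-pixel
#' calibration, `motionAxis()` the motion-axis convention, and
#' `axisPositions()` the detector-plane positions (mm, origin at the image
#' center) of the pixels along the motion axis.
#'
#' @param object a [PortalImage-class].
#' @name pixels
NULL

#' @rdname pixels
#' @export
setMethod("pixels", "PortalImage", function(object) object@pixels)

#' @rdname pixels
#' @export
setMethod("pixelPitch", "PortalImage", function(object) object@pixelPitch)

#' @rdname pixels
#' @export
setMethod("pixelPitch", "Profile", function(object) {
  if (length(object@positions) > 1L) diff(object@positions[1:2]) else NA_real_
})

#' @rdname pixels
#' @export
setMethod("motionAxis", "PortalImage", function(object) object@motionAxis)

#' @rdname pixels
#' @export
setMethod("axisPositions", "PortalImage", function(object) {
  n <- if (object@motionAxis == "cols") ncol(object@pixels)
       else nrow(object@pixels)
  (seq_len(n) - (n + 1) / 2) * object@pixelPitch
})

## positions across the motion axis (the transverse axis), mm
.transversePositions <- function(image) {
  n <- if (image@motionAxis == "cols") nrow(image@pixels)
       else ncol(image@pixels)
  (seq_len(n) - (n + 1) / 2) * image@pixelPitch
}

## +1 if phantom positions increase with time, -1 if they decrease
.dirSign <- function(direction) {
  direction <- match.arg(direction, c("descending", "ascending"))
  if (direction == "descending") -1 else +1
}

## mm at detector plane -> fractional pixel index along the motion axis
.mmToPx <- function(mm, n, pitch) mm / pitch + (n + 1) / 2
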