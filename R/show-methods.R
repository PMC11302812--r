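setMethod("show", "BeamGeometry", function(object) {
  cat(sprintf(
    "BeamGeometry: SAD %g mm, SID %g mm (magnification %.3f), pitch %g mm, image %d x %d\n",
    object@sad, object@sid, magnification(object), object@pixelPitch,
    object@imageShape[1L], object@imageShape[2L]))
})

setMethod("show", "PortalImage", function(object) {
  cat(sprintf(
    "PortalImage: %d x %d px, pitch %g mm, motion along %s, counts %.0f..%.0f\n",
    nrow(object@pixels), ncol(object@pixels), object@pixelPitch,
    object@motionAxis, min(object@pixels), max(object@pixels)))
})

setMethod("show", "BallDetection", function(object) {
  cat(sprintf(
    "BallDetection: center %+.3f mm (px %.2f), depth %.0f counts, FWHM %.2f mm, quality %.2f\n",
    object@center, object@centerPx, object@depth, object@fwhm,
    object@quality))
})

setMethod("show", "VelocityFit", function(object) {
  cat(sprintf(
    "VelocityFit: %.3f mm/s (slope %+.3f, intercept %.3f mm), R^2 %.4f, p %s, n %d\n",
    object@speed, object@signedSlope, object@intercept, object@rSquared,
    ifelse(is.na(object@pValue), "NA",
           format.pval(object@pValue, digits = 3)), object@nPoints))
})

setMethod("show", "DelayMeasurement", function(object) {
  cat(sprintf(
    "DelayMeasurement [%s%s]: delay %.2f ms (dx %.3f mm at %g mm/s), repeat %d\n",
    object@phase,
    if (nzchar(object@beamMode)) paste0(", ", object@beamMode) else "",
    object@delay, object@deltaX, object@velocity, object@repeatIndex))
})

setMethod("show", "BeamModeResult", function(object) {
  cat(sprintf(
    "BeamModeResult [%s, %s]: MDD %.2f mm, delay %.2f +/- %.2f ms (n = %d)\n",
    object@phase, object@beamMode, object@mdd, object@meanDelay, object@sd,
    object@nRepeats))
})

setMethod("show", "SystemSummary", function(object) {
  cat(sprintf(
    "SystemSummary [%s, %s]: %.2f +/- %.2f ms over %d modes (population SD)\n",
    object@system, object@phase, object@mean, object@sd,
    length(object@modesIncluded)))
})

setMethod("show", "ToleranceCheck", function(object) {
  cat(sprintf("ToleranceCheck: measured %.2f ms vs %.2f ms -> %s\n",
              object@measured, object@threshold,
              if (object@pass) "PASS" else "FAIL"))
})
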