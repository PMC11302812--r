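#' Convert a detector-plane displacement to the isocenter plane
#'
#' Positions measured on the imager are magnified by SID/SAD relative to
#' the isocenter plane (similar triangles), so the physical ball
#' displacement is `(pMeas - pRef) * SAD / SID`. The sign is preserved;
#' extending the imager arm (larger SID) scales both measured positions
#' and cancels out of the result.
#'
#' @param pMeas ball position in the motion image, mm at the detector plane.
#' @param pRef ball position in the reference image, mm at the detector
#'   plane.
#' @param geometry a [BeamGeometry-class].
#' @return Displacement in mm at the isocenter plane.
#' @examples
#' displacementIsocenter(11.408, 0, BeamGeometry())  # 7.13 mm
#' @export
displacementIsocenter <- function(pMeas, pRef, geometry) {
  stopifnot(is(geometry, "BeamGeometry"))
  (pMeas - pRef) * geometry@sad / geometry@sid
}

#' Convert a displacement to a time delay
#'
#' The gating latency is the time the phantom needed to travel the
#' measured displacement: `t = dx / v` (ms for dx in mm and v in mm/s,
#' scaled by 1000). A negative displacement (ball short of the reference,
#' i.e. the system gated early) yields a negative delay, reported as-is
#' with a warning rather than clamped.
#'
#' @param deltaX displacement in mm at the isocenter plane.
#' @param velocity phantom speed in mm/s (> 0).
#' @return Delay in ms.
#' @examples
#' delayFromDisplacement(7.13, 24)  # 297.0833 ms
#' @export
delayFromDisplacement <- function(deltaX, velocity) {
  if (!isTRUE(all(is.finite(velocity))) || any(velocity <= 0))
    stop("'velocity' must be positive (mm/s)")
  if (any(deltaX < 0))
    warning("negative displacement: delay reported as negative (gated early)")
  deltaX / velocity * 1000
}

#' Measure the beam-on delay from a reference / snapshot image pair
#'
#' Locates the ball center in both images ([locateBallCenter()]), converts
#' the detector-plane offset to the isocenter plane
#' ([displacementIsocenter()]) with the convention that displacement along
#' the phantom's motion direction is positive, and divides by the phantom
#' speed ([delayFromDisplacement()]).
#'
#' @param reference [PortalImage-class] of the static ball at the beam-on
#'   reference position.
#' @param motion [PortalImage-class] beam-on snapshot.
#' @param geometry a [BeamGeometry-class].
#' @param velocity phantom speed in mm/s.
#' @param direction `"descending"` (default) or `"ascending"`.
#' @param beamMode label stored on the measurement.
#' @param repeatIndex repeat number stored on the measurement.
#' @return A [DelayMeasurement-class].
#' @export
beamOnDelay <- function(reference, motion, geometry, velocity,
                        direction = "descending", beamMode = "",
                        repeatIndex = 1L) {
  s <- .dirSign(direction)
  refDet <- locateBallCenter(reference)
  motDet <- locateBallCenter(motion)
  dx <- s * displacementIsocenter(motDet@center, refDet@center, geometry)
  delay <- deltaXtoDelay(dx, velocity)
  if (abs(delay) > 1000)
    warning(sprintf(
      "implausible beam-on delay %.1f ms (> 1 s); check setup", delay))
  new("DelayMeasurement",
      deltaX = dx, velocity = velocity, delay = delay, phase = "beam_on",
      repeatIndex = as.integer(repeatIndex), beamMode = beamMode,
      diagnostics = list(p_ref_mm = refDet@center, p_meas_mm = motDet@center,
                         ref_quality = refDet@quality,
                         motion_quality = motDet@quality))
}

## delay without the negative-displacement warning (internal)
deltaXtoDelay <- function(deltaX, velocity) {
  stopifnot(velocity > 0)
  deltaX / velocity * 1000
}

## trapezoid cumulative integral of `a` (spacing h) taken along the motion
## direction: the value at x is the integral over everything the ball has
## already swept past when its center reaches x.
.blurTemplate <- function(a, h, dirSign) {
  n <- length(a)
  if (dirSign < 0) {
    c(0, cumsum((a[-1L] + a[-n]) / 2)) * h
  } else {
    rev(c(0, cumsum((rev(a)[-1L] + rev(a)[-n]) / 2))) * h
  }
}

#' Measure the beam-off delay by trailing-edge matching
#'
#' Implements the displaced-reference matching: the reference ball profile
#' is shifted along the motion direction by a candidate displacement `d`
#' (isocenter-plane mm, applied as `d * magnification` on the detector) and
#' compared with the blur trace. Because the trace is a time integral of
#' the moving ball, the shifted reference is first integrated along the
#' motion direction (the profile a ball stopping at that position would
#' leave); both profiles are normalised to unit plateau depth and the sum
#' of squared differences is evaluated over the stop-side half of the
#' trace, from mid-plateau to beyond the stop edge — the region whose shape
#' encodes where the beam switched off. The candidate grid steps 0.25 px
#' coarsely over `search` and is refined to 0.05 px around the minimum.
#'
#' The 50%-crossing stop edge ([locateTraceEdges()]) provides an
#' independent estimate of the same displacement; the absolute discrepancy
#' is returned in the diagnostics and a quality warning is raised when it
#' exceeds 2 px.
#'
#' @param reference [PortalImage-class] of the static ball at the beam-off
#'   reference position.
#' @param trace [PortalImage-class] beam-off blur trace.
#' @param geometry a [BeamGeometry-class].
#' @param velocity phantom speed in mm/s.
#' @param direction `"descending"` (default) or `"ascending"`.
#' @param search numeric length-2: candidate displacement range in
#'   isocenter-plane mm (default 0 to 15, spanning delays up to 625 ms at
#'   24 mm/s).
#' @param beamMode,repeatIndex labels stored on the measurement.
#' @return A [DelayMeasurement-class]; `diagnostics` carries the matched
#'   displacement, the edge-based estimate and their discrepancy in pixels.
#' @export
beamOffDelay <- function(reference, trace, geometry, velocity,
                         direction = "descending", search = c(0, 15),
                         beamMode = "", repeatIndex = 1L) {
  stopifnot(is(trace, "PortalImage"), length(search) == 2L)
  s <- .dirSign(direction)
  M <- magnification(geometry)
  pitch <- trace@pixelPitch

  refDet <- locateBallCenter(reference)
  refProf <- extractProfile(reference)
  refAtt <- .estimateBackground(refProf@intensities) - refProf@intensities
  refAtt[refAtt < 0] <- 0

  trProf <- extractProfile(trace)
  pos <- trProf@positions
  trAtt <- .estimateBackground(trProf@intensities) - trProf@intensities
  depth <- max(trAtt)
  if (depth <= 0) stop("no trace found in the motion image")
  plateau <- stats::median(trAtt[trAtt > 0.8 * depth])
  trNorm <- trAtt / plateau
  edges <- suppressWarnings(locateTraceEdges(trace, direction))

  ## stop-side window: mid-plateau to 1.5 ball widths past the stop edge
  ballW <- if (is.finite(refDet@fwhm)) refDet@fwhm * 1.25 else 10 * pitch
  mid <- (edges[["lead"]] + edges[["stop"]]) / 2
  wLo <- min(mid, edges[["stop"]] + s * 1.5 * ballW)
  wHi <- max(mid, edges[["stop"]] + s * 1.5 * ballW)
  win <- which(pos >= wLo & pos <= wHi)
  if (length(win) < 8L)
    stop("stop-side matching window too small; trace may be degenerate")

  ssd <- function(d) {
    shifted <- stats::approx(refProf@positions, refAtt,
                             pos - s * d * M, rule = 2)$y
    tmpl <- .blurTemplate(shifted, pitch, s)
    tmpl <- tmpl / max(tmpl)
    sum((tmpl[win] - trNorm[win])^2)
  }

  coarseStep <- 0.25 * pitch / M
  grid <- seq(min(search), max(search), by = coarseStep)
  vals <- vapply(grid, ssd, numeric(1))
  i <- which.min(vals)
  if (i == 1L || i == length(grid))
    stop("no interior minimum in the beam-off search range [",
         min(search), ", ", max(search), "] mm; widen 'search'")
  fineStep <- 0.05 * pitch / M
  fine <- seq(grid[i] - coarseStep, grid[i] + coarseStep, by = fineStep)
  dStar <- fine[which.min(vapply(fine, ssd, numeric(1)))]

  ## independent cross-check from the 50%-crossing stop edge
  dEdge <- s * (edges[["stop"]] - refDet@center) / M
  diagPx <- abs(dEdge - dStar) * M / pitch
  if (diagPx > 2)
    warning(sprintf(
      "beam-off diagnostics disagree by %.2f px (matcher %.3f mm vs edge %.3f mm)",
      diagPx, dStar, dEdge))

  delay <- deltaXtoDelay(dStar, velocity)
  new("DelayMeasurement",
      deltaX = dStar, velocity = velocity, delay = delay,
      phase = "beam_off", repeatIndex = as.integer(repeatIndex),
      beamMode = beamMode,
      diagnostics = list(matched_mm = dStar, edge_mm = dEdge,
                         edge_disagreement_px = diagPx,
                         p_ref_mm = refDet@center,
                         stop_edge_mm = edges[["stop"]]))
}

#' Measurement accessors
#'
#' `delayMs()`, `deltaX()`, `phase()` and `beamMode()` read the
#' corresponding fields of a [DelayMeasurement-class] (and, where they
#' apply, of [BeamModeResult-class] / [SystemSummary-class]).
#'
#' @param object a measurement or result object.
#' @name delayMs
NULL

#' @rdname delayMs
#' @export
setMethod("delayMs", "DelayMeasurement", function(object) object@delay)

#' @rdname delayMs
#' @export
setMethod("deltaX", "DelayMeasurement", function(object) object@deltaX)

#' @rdname delayMs
#' @export
setMethod("phase", "DelayMeasurement", function(object) object@phase)

#' @rdname delayMs
#' @export
setMethod("beamMode", "DelayMeasurement", function(object) object@beamMode)

#' @rdname delayMs
#' @export
setMethod("delayMs", "BeamModeResult", function(object) object@meanDelay)

#' @rdname delayMs
#' @export
setMethod("phase", "BeamModeResult", function(object) object@phase)

#' @rdname delayMs
#' @export
setMethod("beamMode", "BeamModeResult", function(object) object@beamMode)

#' @rdname delayMs
#' @export
setMethod("delayMs", "SystemSummary", function(object) object@mean)

#' @rdname delayMs
#' @export
setMethod("phase", "SystemSummary", function(object) object@phase)

#' Ball detection accessors
#'
#' @param object a [BallDetection-class].
#' @name centerMm
NULL

#' @rdname centerMm
#' @export
setMethod("centerMm", "BallDetection", function(object) object@center)

#' @rdname centerMm
#' @export
setMethod("centerPx", "BallDetection", function(object) object@centerPx)

#' @rdname centerMm
#' @export
setMethod("quality", "BallDetection", function(object) object@quality)
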