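#' @import methods
NULL

#' Projection geometry of the linac / EPID arrangement
#'
#' Holds the source-to-axis distance (SAD), source-to-imager distance (SID)
#' and the imager pixel pitch. The ratio SID/SAD is the projective
#' magnification that maps displacements in the isocenter plane onto the
#' detector plane (similar triangles: a ball displacement of d mm at the
#' isocenter appears as d * SID/SAD mm on the imager). Because both the
#' displacement under test and any reference displacement scale by the same
#' factor, extending the imager arm changes detector-plane numbers but never
#' the isocenter-plane result.
#'
#' @slot sad numeric, source-to-axis distance in mm.
#' @slot sid numeric, source-to-imager distance in mm.
#' @slot pixelPitch numeric, detector pixel pitch in mm per pixel.
#' @slot imageShape integer(2), image size as (rows, cols).
#'
#' @seealso [BeamGeometry()] for the user constructor,
#'   [magnification()], [displacementIsocenter()]
#' @exportClass BeamGeometry
setClass("BeamGeometry",
  representation(
    sad = "numeric",
    sid = "numeric",
    pixelPitch = "numeric",
    imageShape = "integer"
  ),
  prototype(
    sad = 1000, sid = 1600, pixelPitch = 0.34, imageShape = c(256L, 256L)
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@sad) != 1L || !is.finite(object@sad) || object@sad <= 0)
      msg <- c(msg, "'sad' must be a single positive number (mm)")
    if (length(object@sid) != 1L || !is.finite(object@sid))
      msg <- c(msg, "'sid' must be a single finite number (mm)")
    else if (object@sid < object@sad)
      msg <- c(msg, "'sid' must be >= 'sad' (imager beyond isocenter)")
    if (length(object@pixelPitch) != 1L || !is.finite(object@pixelPitch) ||
        object@pixelPitch <= 0)
      msg <- c(msg, "'pixelPitch' must be a single positive number (mm)")
    if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
      msg <- c(msg, "'imageShape' must be two integers >= 8 (rows, cols)")
    if (length(msg)) msg else TRUE
  }
)

#' Physical description of the embedded metal ball
#'
#' The Winston-Lutz style cube carries a metal ball that casts a
#' high-contrast circular footprint on the portal image. The ball is
#' modelled as an opaque disk of the stated diameter (at the isocenter
#' plane) that attenuates the transmitted signal by `contrast` at full
#' coverage.
#'
#' @slot diameter numeric, physical ball diameter in mm at the isocenter plane.
#' @slot contrast numeric in (0, 1], fractional attenuation at the ball center.
#' @slot backgroundLevel numeric, open-field detector counts.
#'
#' @exportClass BallSpec
setClass("BallSpec",
  representation(
    diameter = "numeric",
    contrast = "numeric",
    backgroundLevel = "numeric"
  ),
  prototype(diameter = 6, contrast = 0.5, backgroundLevel = 40000),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(is.finite(object@diameter)) || object@diameter <= 0)
      msg <- c(msg, "'diameter' must be positive (mm)")
    if (!isTRUE(is.finite(object@contrast)) ||
        object@contrast <= 0 || object@contrast > 1)
      msg <- c(msg, "'contrast' must be in (0, 1]")
    if (!isTRUE(is.finite(object@backgroundLevel)) ||
        object@backgroundLevel <= 0)
      msg <- c(msg, "'backgroundLevel' must be positive (counts)")
    if (length(msg)) msg else TRUE
  }
)

#' Gating window configuration
#'
#' The gating window is the band of phantom positions within which the beam
#' is allowed on, described by its center level and halfwidth. The
#' reference position for beam-on is the window boundary the phantom
#' crosses on entry, and for beam-off the boundary crossed on exit; which
#' boundary is which depends on the direction of travel, so the direction
#' is part of the configuration rather than inferred from images.
#'
#' @slot center numeric, gate center level in mm.
#' @slot halfwidth numeric >= 0, half the gate width in mm (default 1).
#' @slot direction character, `"descending"` (positions decrease with time)
#'   or `"ascending"`.
#'
#' @seealso [gateReferencePositions()]
#' @exportClass GateConfig
setClass("GateConfig",
  representation(
    center = "numeric",
    halfwidth = "numeric",
    direction = "character"
  ),
  prototype(center = 1, halfwidth = 1, direction = "descending"),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(is.finite(object@center)))
      msg <- c(msg, "'center' must be a finite number (mm)")
    if (!isTRUE(is.finite(object@halfwidth)) || object@halfwidth < 0)
      msg <- c(msg, "'halfwidth' must be >= 0 (mm)")
    if (length(object@direction) != 1L ||
        !object@direction %in% c("descending", "ascending"))
      msg <- c(msg, "'direction' must be \"descending\" or \"ascending\"")
    if (length(msg)) msg else TRUE
  }
)

#' Simulation scenario for synthetic portal images
#'
#' Bundles everything the renderer needs to draw a reference image, a
#' beam-on snapshot, or a beam-off blur trace with a known ground-truth
#' delay. Positions and velocities are expressed at the isocenter plane;
#' the renderer applies the projective magnification.
#'
#' @slot geometry a [BeamGeometry-class].
#' @slot ball a [BallSpec-class].
#' @slot velocity numeric > 0, phantom speed in mm/s at the isocenter plane.
#' @slot trueDelay numeric >= 0, ground-truth delay in ms.
#' @slot phase character, `"beam_on"` or `"beam_off"`.
#' @slot direction character, `"descending"` or `"ascending"`.
#' @slot referencePosition numeric, gate reference position in mm
#'   (isocenter plane) for the simulated phase.
#' @slot beamDuration numeric, beam-on time in s (beam-off scenarios).
#' @slot rampTime numeric >= 0, linear dose-rate ramp-down duration in ms
#'   applied to the end of a beam-off trace (0 = hard cutoff).
#' @slot noiseSigma numeric >= 0, additive Gaussian noise in counts.
#' @slot seed integer, RNG seed for the noise draw.
#'
#' @exportClass SimScenario
setClass("SimScenario",
  representation(
    geometry = "BeamGeometry",
    ball = "BallSpec",
    velocity = "numeric",
    trueDelay = "numeric",
    phase = "character",
    direction = "character",
    referencePosition = "numeric",
    beamDuration = "numeric",
    rampTime = "numeric",
    noiseSigma = "numeric",
    seed = "integer"
  ),
  prototype(
    velocity = 24, trueDelay = 0, phase = "beam_on", direction = "descending",
    referencePosition = 0, beamDuration = 1, rampTime = 0, noiseSigma = 0,
    seed = 1L
  ),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(is.finite(object@velocity)) || object@velocity <= 0)
      msg <- c(msg, "'velocity' must be positive (mm/s)")
    if (!isTRUE(is.finite(object@trueDelay)) || object@trueDelay < 0)
      msg <- c(msg, "'trueDelay' must be >= 0 (ms)")
    if (!object@phase %in% c("beam_on", "beam_off"))
      msg <- c(msg, "'phase' must be \"beam_on\" or \"beam_off\"")
    if (!object@direction %in% c("descending", "ascending"))
      msg <- c(msg, "'direction' must be \"descending\" or \"ascending\"")
    if (!isTRUE(is.finite(object@referencePosition)))
      msg <- c(msg, "'referencePosition' must be finite (mm)")
    if (!isTRUE(is.finite(object@rampTime)) || object@rampTime < 0)
      msg <- c(msg, "'rampTime' must be >= 0 (ms)")
    if (!isTRUE(is.finite(object@noiseSigma)) || object@noiseSigma < 0)
      msg <- c(msg, "'noiseSigma' must be >= 0 (counts)")
    if (object@phase == "beam_off") {
      if (!isTRUE(is.finite(object@beamDuration)) || object@beamDuration <= 0)
        msg <- c(msg, "'beamDuration' must be positive (s) for beam_off")
      else if (object@beamDuration * object@velocity < object@ball@diameter)
        msg <- c(msg,
          "beam_off travel must cover at least one ball diameter")
    }
    if (length(msg)) msg else TRUE
  }
)

#' A portal image with its physical pixel calibration
#'
#' A 2-D grid of detector counts plus the pixel pitch and the convention
#' for which image axis carries the phantom motion. Positions along either
#' axis are measured in mm at the detector plane from the image center;
#' along the motion axis ("cols") position increases with column index,
#' and a descending phantom maps to decreasing column position.
#'
#' @slot pixels numeric matrix of detector counts (rows x cols), all
#'   finite and >= 0.
#' @slot pixelPitch numeric, mm per pixel at the detector plane.
#' @slot motionAxis character, `"cols"` (default) or `"rows"`.
#'
#' @exportClass PortalImage
setClass("PortalImage",
  representation(
    pixels = "matrix",
    pixelPitch = "numeric",
    motionAxis = "character"
  ),
  prototype(pixelPitch = 0.34, motionAxis = "cols"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@pixels) || length(dim(object@pixels)) != 2L)
      msg <- c(msg, "'pixels' must be a numeric matrix")
    else if (!all(is.finite(object@pixels)) || any(object@pixels < 0))
      msg <- c(msg, "'pixels' must be finite and >= 0")
    if (!isTRUE(is.finite(object@pixelPitch)) || object@pixelPitch <= 0)
      msg <- c(msg, "'pixelPitch' must be positive (mm)")
    if (length(object@motionAxis) != 1L ||
        !object@motionAxis %in% c("cols", "rows"))
      msg <- c(msg, "'motionAxis' must be \"cols\" or \"rows\"")
    if (length(msg)) msg else TRUE
  }
)

#' A 1-D motion-axis intensity profile
#'
#' Intensities averaged over a transverse band centered on the ball,
#' indexed by detector-plane position in mm (origin at image center).
#'
#' @slot positions numeric, strictly increasing, uniformly spaced (mm).
#' @slot intensities numeric, band-averaged counts.
#' @slot bandHalfwidth integer, transverse averaging half-width in pixels.
#'
#' @exportClass Profile
setClass("Profile",
  representation(
    positions = "numeric",
    intensities = "numeric",
    bandHalfwidth = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@positions) != length(object@intensities))
      msg <- c(msg, "'positions' and 'intensities' lengths differ")
    if (length(object@positions) > 1L) {
      d <- diff(object@positions)
      if (any(d <= 0) || diff(range(d)) > 1e-9 * max(d))
        msg <- c(msg, "'positions' must be strictly increasing and uniform")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Sub-pixel ball detection result
#'
#' @slot center numeric, ball center in mm at the detector plane.
#' @slot centerPx numeric, the same center as fractional pixel index.
#' @slot depth numeric > 0, attenuation amplitude in counts.
#' @slot fwhm numeric, full width at half maximum of the attenuation
#'   profile in mm.
#' @slot quality numeric in [0, 1], heuristic detection quality from the
#'   depth-to-background-noise ratio (1 = noise-free).
#'
#' @exportClass BallDetection
setClass("BallDetection",
  representation(
    center = "numeric",
    centerPx = "numeric",
    depth = "numeric",
    fwhm = "numeric",
    quality = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(is.finite(object@center)))
      msg <- c(msg, "'center' must be finite (mm)")
    if (!isTRUE(is.finite(object@depth)) || object@depth <= 0)
      msg <- c(msg, "'depth' must be positive for a valid detection")
    if (!isTRUE(object@quality >= 0 && object@quality <= 1))
      msg <- c(msg, "'quality' must be in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Result of a linear velocity fit
#'
#' Ordinary least-squares line through (time, position) samples of the
#' phantom waveform, restricted to a stated time window.
#'
#' @slot speed numeric, absolute slope in mm/s.
#' @slot signedSlope numeric, signed slope in mm/s.
#' @slot intercept numeric, mm.
#' @slot rSquared numeric in [0, 1].
#' @slot pValue numeric in [0, 1], two-sided slope t-test (NA when n = 2,
#'   where the line is exact and no residual degrees of freedom remain).
#' @slot nPoints integer >= 2.
#'
#' @exportClass VelocityFit
setClass("VelocityFit",
  representation(
    speed = "numeric",
    signedSlope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    pValue = "numeric",
    nPoints = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(all.equal(object@speed, abs(object@signedSlope))))
      msg <- c(msg, "'speed' must equal |signedSlope|")
    if (!isTRUE(object@rSquared >= -1e-12 && object@rSquared <= 1 + 1e-12))
      msg <- c(msg, "'rSquared' must be in [0, 1]")
    if (object@nPoints < 2L)
      msg <- c(msg, "'nPoints' must be >= 2")
    if (length(msg)) msg else TRUE
  }
)

#' One repeat's delay measurement
#'
#' Houses the displacement-to-delay conversion t = dx / v: `deltaX` is the
#' ball displacement at the isocenter plane (positive along the phantom's
#' motion direction), `velocity` the phantom speed, and `delay` their
#' ratio in ms.
#'
#' @slot deltaX numeric, mm at the isocenter plane.
#' @slot velocity numeric > 0, mm/s.
#' @slot delay numeric, ms; always `deltaX / velocity * 1000`.
#' @slot phase character, `"beam_on"` or `"beam_off"`.
#' @slot repeatIndex integer, which repeat this is.
#' @slot beamMode character label, e.g. `"6xFFF, 1200"`.
#' @slot diagnostics list of method diagnostics (e.g. the edge-based
#'   cross-check of the beam-off matcher).
#'
#' @exportClass DelayMeasurement
setClass("DelayMeasurement",
  representation(
    deltaX = "numeric",
    velocity = "numeric",
    delay = "numeric",
    phase = "character",
    repeatIndex = "integer",
    beamMode = "character",
    diagnostics = "list"
  ),
  prototype(repeatIndex = 1L, beamMode = "", diagnostics = list()),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(is.finite(object@velocity)) || object@velocity <= 0)
      msg <- c(msg, "'velocity' must be positive (mm/s)")
    else if (abs(object@delay - object@deltaX / object@velocity * 1000) >
             1e-9 * max(1, abs(object@delay)))
      msg <- c(msg, "'delay' must equal deltaX / velocity * 1000")
    if (!object@phase %in% c("beam_on", "beam_off"))
      msg <- c(msg, "'phase' must be \"beam_on\" or \"beam_off\"")
    if (length(msg)) msg else TRUE
  }
)

#' Aggregated result for one beam mode
#'
#' Mean distance discrepancy (MDD, the mean isocenter-plane displacement
#' over repeats), mean delay and the sample standard deviation (divisor
#' n - 1) of the delay over repeats.
#'
#' @slot beamMode character label.
#' @slot phase character, `"beam_on"` or `"beam_off"`.
#' @slot mdd numeric, mm.
#' @slot meanDelay numeric, ms.
#' @slot sd numeric >= 0, ms (sample SD over repeats).
#' @slot nRepeats integer >= 1.
#' @slot velocity numeric, mm/s shared by the repeats.
#'
#' @exportClass BeamModeResult
setClass("BeamModeResult",
  representation(
    beamMode = "character",
    phase = "character",
    mdd = "numeric",
    meanDelay = "numeric",
    sd = "numeric",
    nRepeats = "integer",
    velocity = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (object@sd < 0) msg <- c(msg, "'sd' must be >= 0")
    if (object@nRepeats < 1L) msg <- c(msg, "'nRepeats' must be >= 1")
    if (isTRUE(is.finite(object@velocity)) && object@velocity > 0 &&
        abs(object@meanDelay - object@mdd / object@velocity * 1000) > 1e-6)
      msg <- c(msg, "'meanDelay' must equal mdd / velocity * 1000")
    if (length(msg)) msg else TRUE
  }
)

#' Cross-energy summary for one gating system and phase
#'
#' Arithmetic mean and population standard deviation (divisor N) of the
#' per-beam-mode mean delays.
#'
#' @slot system character label, e.g. `"Catalyst"`.
#' @slot phase character, `"beam_on"` or `"beam_off"`.
#' @slot mean numeric, ms.
#' @slot sd numeric >= 0, ms (population SD across modes).
#' @slot modesIncluded character vector of beam-mode labels.
#'
#' @exportClass SystemSummary
setClass("SystemSummary",
  representation(
    system = "character",
    phase = "character",
    mean = "numeric",
    sd = "numeric",
    modesIncluded = "character"
  ),
  validity = function(object) {
    if (object@sd < 0) "'sd' must be >= 0" else TRUE
  }
)

#' Action-level check on a system summary
#'
#' @slot threshold numeric > 0, ms (from configuration, never hard-coded).
#' @slot measured numeric, ms.
#' @slot pass logical; TRUE iff measured <= threshold.
#'
#' @exportClass ToleranceCheck
setClass("ToleranceCheck",
  representation(
    threshold = "numeric",
    measured = "numeric",
    pass = "logical"
  ),
  validity = function(object) {
    if (!identical(object@pass, object@measured <= object@threshold))
      "'pass' must be measured <= threshold" else TRUE
  }
)
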