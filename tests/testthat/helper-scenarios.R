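# shared fixture builders; everything is generated in code at test time

# absolute-difference assertion: pixel-scale tolerances must not be
# rescaled by the magnitude of the expected value (as expect_equal's
# relative tolerance would)
expect_close <- function(actual, expected, tol, label = NULL) {
  testthat::expect_lt(max(abs(actual - expected)), tol, label = label)
}

stdGeometry <- function(...) BeamGeometry(...)

stdGate <- function(direction = "descending")
  GateConfig(center = 1, halfwidth = 1, direction = direction)

# one detector pixel expressed as a delay at the standard conditions
# (0.34 mm pitch, magnification 1.6, 24 mm/s)
pixelEquivalentMs <- function(geometry = stdGeometry(), velocity = 24)
  geometry@pixelPitch / magnification(geometry) / velocity * 1000

beamOnPair <- function(delayMs, noiseSigma = 0, seed = 1L,
                       geometry = stdGeometry(), gate = stdGate(),
                       velocity = 24, ball = BallSpec()) {
  refPos <- gateReferencePositions(gate)[["beamOn"]]
  sc <- SimScenario(geometry = geometry, ball = ball, velocity = velocity,
                    trueDelay = delayMs, phase = "beam_on",
                    direction = gate@direction, referencePosition = refPos,
                    noiseSigma = noiseSigma, seed = seed)
  scRef <- SimScenario(geometry = geometry, ball = ball, velocity = velocity,
                       phase = "beam_on", direction = gate@direction,
                       referencePosition = refPos, noiseSigma = noiseSigma,
                       seed = seed + 1000L)
  list(reference = renderReference(scRef), motion = renderBeamOnSnapshot(sc),
       gate = gate, geometry = geometry, velocity = velocity)
}

beamOffPair <- function(delayMs, noiseSigma = 0, seed = 1L,
                        geometry = stdGeometry(), gate = stdGate(),
                        velocity = 24, ball = BallSpec(), beamDuration = 1) {
  refPos <- gateReferencePositions(gate)[["beamOff"]]
  sc <- SimScenario(geometry = geometry, ball = ball, velocity = velocity,
                    trueDelay = delayMs, phase = "beam_off",
                    direction = gate@direction, referencePosition = refPos,
                    beamDuration = beamDuration, noiseSigma = noiseSigma,
                    seed = seed)
  scRef <- SimScenario(geometry = geometry, ball = ball, velocity = velocity,
                       phase = "beam_off", direction = gate@direction,
                       referencePosition = refPos,
                       beamDuration = beamDuration, noiseSigma = noiseSigma,
                       seed = seed + 1000L)
  list(reference = renderReference(scRef), trace = renderBeamOffTrace(sc),
       gate = gate, geometry = geometry, velocity = velocity)
}

# independent exhaustive oracle: thresholded center of mass along the
# motion axis over ALL pixels of the 2-D image (excess weighting above
# 50% of the maximum attenuation; background = 2-D median, valid because
# the ball covers a small fraction of the image)
comOracle <- function(image) {
  px <- pixels(image)
  bg <- median(px)
  att <- bg - px
  w <- pmax(att - max(att) / 2, 0)
  colPos <- matrix(axisPositions(image), nrow(px), ncol(px), byrow = TRUE)
  sum(colPos * w) / sum(w)
}

newMeasurement <- function(delay, velocity = 24, phase = "beam_on",
                           beamMode = "6x, 600", repeatIndex = 1L) {
  new("DelayMeasurement", deltaX = delay * velocity / 1000,
      velocity = velocity, delay = delay, phase = phase,
      repeatIndex = as.integer(repeatIndex), beamMode = beamMode,
      diagnostics = list())
}
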