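test_that("profile extraction averages the transverse band", {
  img <- PortalImage(matrix(500, 64, 64))
  prof <- extractProfile(img, bandHalfwidth = 2)
  expect_true(all(prof@intensities == 500))
  expect_equal(length(prof@positions), 64)
  expect_equal(mean(prof@positions), 0)
  expect_error(extractProfile(img, bandHalfwidth = 40), "outside the image")
})

test_that("located center is insensitive to the band halfwidth", {
  img <- renderReference(SimScenario(referencePosition = 0))
  c0 <- locateBallCenter(img, bandHalfwidth = 0)@center
  c3 <- locateBallCenter(img, bandHalfwidth = 3)@center
  expect_close(c0, c3, 0.05 * 0.34)
  # auto band picks roughly the ball radius (6 mm * 1.6 / 2 / 0.34 px)
  pa <- extractProfile(img)
  expect_close(as.numeric(pa@bandHalfwidth), 6 * 1.6 / 2 / 0.34, 3)
})

test_that("sub-pixel centers are recovered to 0.1 px across offsets", {
  pitchIso <- 0.34 / 1.6
  for (sub in c(0, 0.25, 0.5, 0.75)) {
    posIso <- (10 + sub) * pitchIso
    det <- locateBallCenter(renderReference(
      SimScenario(referencePosition = posIso)))
    expect_close(det@center, posIso * 1.6, 0.1 * 0.34,
                 label = sprintf("sub-pixel offset %.2f", sub))
  }
})

test_that("a 0.3 px re-rendered shift is detected to 0.1 px", {
  pitchIso <- 0.34 / 1.6
  d1 <- locateBallCenter(renderReference(SimScenario(referencePosition = 2)))
  d2 <- locateBallCenter(renderReference(
    SimScenario(referencePosition = 2 + 0.3 * pitchIso)))
  expect_close(d2@center - d1@center, 0.3 * 0.34, 0.1 * 0.34)
})

test_that("center is invariant to affine intensity changes", {
  img <- renderReference(SimScenario(referencePosition = 1.3))
  base <- locateBallCenter(img)@center
  shifted <- PortalImage(pixels(img) + 100, pixelPitch = 0.34)
  scaled <- PortalImage(pixels(img) * 1.7, pixelPitch = 0.34)
  expect_close(locateBallCenter(shifted)@center, base, 1e-6 * 0.34)
  expect_close(locateBallCenter(scaled)@center, base, 1e-6 * 0.34)
})

test_that("noisy detections stay within half a pixel", {
  # noise at 2% of the contrast depth (0.02 * 0.5 * 40000 = 400 counts)
  errs <- vapply(1:30, function(k) {
    img <- renderReference(SimScenario(referencePosition = 2,
                                       noiseSigma = 400, seed = 100L + k))
    locateBallCenter(img)@center - 2 * 1.6
  }, numeric(1))
  expect_lt(max(abs(errs)) / 0.34, 0.5)
})

test_that("detection errors are raised for missing or ambiguous balls", {
  set.seed(31)
  noise <- PortalImage(matrix(abs(rnorm(64 * 64, 500, 2)), 64, 64))
  expect_error(locateBallCenter(noise), "no ball found")

  # two balls in one image -> ambiguous
  img1 <- pixels(renderReference(SimScenario(referencePosition = -8)))
  img2 <- pixels(renderReference(SimScenario(referencePosition = 8)))
  both <- PortalImage(pmin(img1, img2), pixelPitch = 0.34)
  expect_error(locateBallCenter(both), "ambiguous")
})

test_that("detection reports depth, FWHM and quality", {
  det <- locateBallCenter(renderReference(SimScenario(referencePosition = 0)))
  expect_close(det@depth, 0.5 * 40000, 200)
  # band-averaged dome: half depth roughly sqrt(3)/2 of the radius out
  expect_close(det@fwhm, 6 * 1.6 * sqrt(3) / 2, 0.6)
  expect_equal(det@quality, 1)
  noisy <- locateBallCenter(renderReference(
    SimScenario(referencePosition = 0, noiseSigma = 400, seed = 5L)))
  expect_true(noisy@quality > 0 && noisy@quality <= 1)
})

test_that("trace edges mirror when the motion direction flips", {
  mkTrace <- function(direction) {
    refPos <- gateReferencePositions(stdGate(direction))[["beamOff"]]
    renderBeamOffTrace(SimScenario(trueDelay = 100, phase = "beam_off",
                                   direction = direction,
                                   referencePosition = refPos,
                                   beamDuration = 1))
  }
  eD <- locateTraceEdges(mkTrace("descending"), "descending")
  eA <- locateTraceEdges(mkTrace("ascending"), "ascending")
  # gate is symmetric about 1 mm: ascending run mirrors the descending one
  # about the gate center's detector position
  cDet <- 1 * 1.6
  expect_close(eA[["stop"]] - cDet, -(eD[["stop"]] - cDet), 0.5 * 0.34)
  expect_close(eA[["lead"]] - cDet, -(eD[["lead"]] - cDet), 0.5 * 0.34)
})

test_that("a short trace warns but still returns edges", {
  sc <- SimScenario(trueDelay = 0, phase = "beam_off",
                    referencePosition = 0, beamDuration = 0.3)
  expect_warning(e <- locateTraceEdges(renderBeamOffTrace(sc), "descending"),
                 "degenerate trace")
  expect_true(all(is.finite(e)))
})
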