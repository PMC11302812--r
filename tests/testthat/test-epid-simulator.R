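test_that("reference render places the magnified ball footprint correctly", {
  # centered ball: image is mirror-symmetric about the central column gap
  sc <- SimScenario(referencePosition = 0)
  img <- renderReference(sc)
  px <- pixels(img)
  expect_equal(px, px[, rev(seq_len(ncol(px)))], tolerance = 1e-12)
  expect_close(comOracle(img), 0, 1e-6)

  # 2 mm at isocenter -> 2 * 1.6 / 0.34 = 9.412 px offset on the detector
  sc2 <- SimScenario(referencePosition = 2)
  det <- locateBallCenter(renderReference(sc2))
  expect_close(det@center, 2 * 1.6, 0.05 * 0.34)
  n <- ncol(px)
  expect_close(det@centerPx - (n + 1) / 2, 2 * 1.6 / 0.34, 0.05)
})

test_that("renders are deterministic for a fixed seed", {
  sc <- SimScenario(noiseSigma = 300, seed = 11L)
  expect_identical(pixels(renderReference(sc)),
                   pixels(renderReference(sc)))
  sc2 <- SimScenario(noiseSigma = 300, seed = 12L)
  expect_false(identical(pixels(renderReference(sc)),
                         pixels(renderReference(sc2))))
})

test_that("attenuated flux is conserved as the ball moves", {
  base <- SimScenario(referencePosition = 0)
  flux0 <- sum(base@ball@backgroundLevel - pixels(renderReference(base)))
  for (pos in c(-5, 2, 7.3)) {
    sc <- SimScenario(referencePosition = pos)
    flux <- sum(sc@ball@backgroundLevel - pixels(renderReference(sc)))
    expect_lt(abs(flux - flux0) / flux0, 1e-3)
  }
})

test_that("beam-on snapshot displaces the ball by velocity * delay", {
  # zero delay: identical to the reference
  sc0 <- SimScenario(trueDelay = 0, referencePosition = 2)
  expect_equal(pixels(renderBeamOnSnapshot(sc0)),
               pixels(renderReference(sc0)), tolerance = 1e-12)

  # 297.08 ms at 24 mm/s: 7.13 mm at the isocenter plane (descending)
  sc <- SimScenario(trueDelay = 297.08, referencePosition = 2)
  ref <- locateBallCenter(renderReference(sc))
  mot <- locateBallCenter(renderBeamOnSnapshot(sc))
  expect_close((ref@center - mot@center) / 1.6, 7.1299, 0.01)

  # 100 ms: 3.84 mm displacement at the detector plane
  sc3 <- SimScenario(trueDelay = 100, referencePosition = 2)
  mot3 <- locateBallCenter(renderBeamOnSnapshot(sc3))
  expect_close(ref@center - mot3@center, 24 * 0.1 * 1.6, 0.02)
})

test_that("doubling SID doubles detector displacements only", {
  g1 <- BeamGeometry(sid = 1600)
  g2 <- BeamGeometry(sid = 3200, imageShape = c(384L, 384L))
  off1 <- vapply(c(0, 2), function(p) locateBallCenter(
    renderReference(SimScenario(geometry = g1, referencePosition = p))
  )@center, numeric(1))
  off2 <- vapply(c(0, 2), function(p) locateBallCenter(
    renderReference(SimScenario(geometry = g2, referencePosition = p))
  )@center, numeric(1))
  expect_close(diff(off2), 2 * diff(off1), 2 * 0.05 * 0.34)
  # isocenter-plane displacement unchanged
  expect_close(displacementIsocenter(off2[2], off2[1], g2),
               displacementIsocenter(off1[2], off1[1], g1),
               0.5 * 0.34 / 1.6)
})

test_that("trace footprint has the geometric extent of the swept disk", {
  sc <- SimScenario(trueDelay = 0, phase = "beam_off",
                    referencePosition = 0, beamDuration = 1)
  img <- renderBeamOffTrace(sc)
  px <- pixels(img)
  att <- sc@ball@backgroundLevel - px
  cols <- which(apply(att, 2, max) > 1e-6 * max(att))
  extentPx <- max(cols) - min(cols) + 1
  expectPx <- (6 + 24 * 1) * 1.6 / 0.34
  expect_close(extentPx, expectPx, 1.5)
})

test_that("trace 50% stop edge sits at the ball's stop center", {
  # time-integrated trace: every row's stop ramp crosses half its plateau
  # exactly where the ball center stopped
  for (d in c(0, 97.69)) {
    sc <- SimScenario(trueDelay = d, phase = "beam_off",
                      referencePosition = 0, beamDuration = 1)
    edges <- locateTraceEdges(renderBeamOffTrace(sc), "descending")
    stopIso <- -24 * d / 1000  # descending from the 0 mm exit reference
    expect_close(edges[["stop"]], stopIso * 1.6, 0.5 * 0.34,
                 label = sprintf("stop edge at %g ms", d))
    expect_close(edges[["lead"]] - edges[["stop"]], 24 * 1 * 1.6, 1 * 0.34)
  }
})

test_that("stop-side trace profile equals the blur integral of the ball", {
  sc <- SimScenario(trueDelay = 97.69, phase = "beam_off",
                    referencePosition = 0, beamDuration = 1)
  tr <- renderBeamOffTrace(sc)
  ref <- renderReference(sc)
  trProf <- extractProfile(tr)
  refProf <- extractProfile(ref)
  pos <- trProf@positions
  trAtt <- max(trProf@intensities) - trProf@intensities
  trNorm <- trAtt / median(trAtt[trAtt > 0.8 * max(trAtt)])
  # shift the static profile to the true stop position and integrate it
  # along the (descending) motion direction
  shift <- (-24 * 0.09769 - 0) * 1.6
  refAtt <- max(refProf@intensities) - refProf@intensities
  shifted <- approx(refProf@positions, refAtt, pos - shift, rule = 2)$y
  tmpl <- gatelag:::.blurTemplate(shifted, 0.34, -1)
  tmpl <- tmpl / max(tmpl)
  stopDet <- shift
  win <- pos > stopDet - 1.5 * 6 * 1.6 / 2 & pos < stopDet + 1.5 * 6 * 1.6 / 2
  expect_lt(max(abs(tmpl[win] - trNorm[win])), 0.01)
})

test_that("ramp-down stretches the stop edge without moving the lead edge", {
  sc0 <- SimScenario(trueDelay = 0, phase = "beam_off",
                     referencePosition = 0, beamDuration = 1)
  scR <- SimScenario(trueDelay = 0, phase = "beam_off",
                     referencePosition = 0, beamDuration = 1,
                     rampTime = 100)
  e0 <- locateTraceEdges(renderBeamOffTrace(sc0), "descending")
  eR <- locateTraceEdges(renderBeamOffTrace(scR), "descending")
  expect_close(eR[["lead"]], e0[["lead"]], 0.5 * 0.34)
  # linear ramp moves the 50% crossing upstream of the hard-cutoff edge
  expect_gt(eR[["stop"]], e0[["stop"]])
})

test_that("footprints outside the image raise geometry errors", {
  expect_error(renderReference(SimScenario(referencePosition = 40)),
               "outside the image")
  expect_error(renderBeamOffTrace(
    SimScenario(phase = "beam_off", referencePosition = 0,
                beamDuration = 4)), "outside the image")
})

test_that("scenario validity guards impossible setups", {
  expect_error(SimScenario(velocity = -1), "velocity")
  expect_error(SimScenario(trueDelay = -5), "trueDelay")
  expect_error(SimScenario(phase = "beam_off", beamDuration = 0.1),
               "ball diameter")
})
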