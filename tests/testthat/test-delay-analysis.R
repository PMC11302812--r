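test_that("displacement converts detector to isocenter plane by SAD/SID", {
  g <- BeamGeometry()
  expect_equal(displacementIsocenter(11.408, 0, g), 7.13, tolerance = 1e-9)
  expect_equal(displacementIsocenter(3.2, 3.2, g), 0)
  expect_equal(displacementIsocenter(0, 3.2, g), -2)
  g2 <- BeamGeometry(sid = 3200)
  expect_equal(displacementIsocenter(22.816, 0, g2), 7.13, tolerance = 1e-9)
})

test_that("displacement-to-delay conversion reproduces printed values", {
  expect_equal(round(delayFromDisplacement(7.13, 24), 2), 297.08)
  expect_equal(round(delayFromDisplacement(2.40, 24), 2), 100.00)
  expect_equal(delayFromDisplacement(0, 17), 0)
  expect_error(delayFromDisplacement(1, 0), "velocity")
  expect_error(delayFromDisplacement(1, -24), "velocity")
  expect_warning(d <- delayFromDisplacement(-2.4, 24), "negative")
  expect_equal(d, -100)
})

test_that("beam-on delay round-trips through the simulator", {
  tolMs <- pixelEquivalentMs()  # 8.854 ms: one detector pixel at 24 mm/s
  pair <- beamOnPair(100)
  m <- beamOnDelay(pair$reference, pair$motion, pair$geometry, 24)
  expect_close(m@delay, 100, tolMs)
  expect_equal(m@deltaX / 24 * 1000, m@delay)
  expect_identical(m@phase, "beam_on")

  # identical images give exactly zero
  m0 <- beamOnDelay(pair$reference, pair$reference, pair$geometry, 24)
  expect_equal(m0@delay, 0)
})

test_that("five noisy beam-on repeats average close to the truth", {
  ms <- lapply(1:5, function(k) {
    pair <- beamOnPair(300, noiseSigma = 400, seed = 200L + k)
    beamOnDelay(pair$reference, pair$motion, pair$geometry, 24)
  })
  delays <- vapply(ms, delayMs, numeric(1))
  expect_lt(abs(mean(delays) - 300), 10)
  expect_gte(sd(delays), 0)
})

test_that("beam-on estimate is linear in the true delay", {
  est <- vapply(c(100, 200), function(d) {
    pair <- beamOnPair(d)
    delayMs(beamOnDelay(pair$reference, pair$motion, pair$geometry, 24))
  }, numeric(1))
  expect_close(est[2], 2 * est[1], 2 * pixelEquivalentMs())
})

test_that("declared velocity rescales the delay as 1/v exactly", {
  pair <- beamOnPair(150)
  m24 <- beamOnDelay(pair$reference, pair$motion, pair$geometry, 24)
  m12 <- beamOnDelay(pair$reference, pair$motion, pair$geometry, 12)
  expect_close(m12@delay, 2 * m24@delay, 1e-9)
  expect_close(m12@deltaX, m24@deltaX, 1e-12)
})

test_that("extending the imager does not change the measured delay", {
  g2 <- BeamGeometry(sid = 3200, imageShape = c(384L, 384L))
  onA <- beamOnPair(100)
  onB <- beamOnPair(100, geometry = g2)
  expect_close(
    delayMs(beamOnDelay(onB$reference, onB$motion, g2, 24)),
    delayMs(beamOnDelay(onA$reference, onA$motion, stdGeometry(), 24)),
    0.5 * pixelEquivalentMs())
  # shorter travel so the doubled-magnification trace stays on the imager
  offA <- beamOffPair(100, beamDuration = 0.6)
  offB <- beamOffPair(100, geometry = g2, beamDuration = 0.6)
  expect_close(
    delayMs(beamOffDelay(offB$reference, offB$trace, g2, 24)),
    delayMs(beamOffDelay(offA$reference, offA$trace, stdGeometry(), 24)),
    0.5 * pixelEquivalentMs())
})

test_that("beam-off matching recovers the stop displacement", {
  tolMs <- pixelEquivalentMs()
  # zero delay: alignment at zero shift (within half a pixel)
  p0 <- beamOffPair(0, beamDuration = 0.8)
  m0 <- beamOffDelay(p0$reference, p0$trace, p0$geometry, 24,
                     search = c(-2, 6))
  expect_lt(abs(m0@delay), 0.5 * tolMs)

  # the printed 97.69 ms case: stop 2.344 mm past the exit reference
  p <- beamOffPair(97.69)
  m <- beamOffDelay(p$reference, p$trace, p$geometry, 24)
  expect_close(m@delay, 97.69, tolMs)
  expect_close(m@deltaX, 2.344, 0.34 / 1.6)
  # edge-based diagnostic agrees with the matcher
  expect_lt(m@diagnostics$edge_disagreement_px, 2)
})

test_that("beam-off matching is symmetric under direction flip", {
  dD <- local({
    p <- beamOffPair(120, gate = stdGate("descending"))
    delayMs(beamOffDelay(p$reference, p$trace, p$geometry, 24, "descending"))
  })
  dA <- local({
    p <- beamOffPair(120, gate = stdGate("ascending"))
    delayMs(beamOffDelay(p$reference, p$trace, p$geometry, 24, "ascending"))
  })
  expect_close(dA, dD, 0.5 * pixelEquivalentMs())
})

test_that("beam-off grid search matches a fine brute-force argmin", {
  # rebuild the objective independently and scan it at 0.01 px steps
  p <- beamOffPair(97.69)
  m <- beamOffDelay(p$reference, p$trace, p$geometry, 24)
  M <- magnification(p$geometry)
  pitch <- pixelPitch(p$trace)

  refProf <- extractProfile(p$reference)
  refAtt <- max(refProf@intensities) - refProf@intensities
  trProf <- extractProfile(p$trace)
  pos <- trProf@positions
  trAtt <- max(trProf@intensities) - trProf@intensities
  plat <- median(trAtt[trAtt > 0.8 * max(trAtt)])
  edges <- locateTraceEdges(p$trace, "descending")
  det <- locateBallCenter(p$reference)
  ballW <- det@fwhm * 1.25
  wLo <- edges[["stop"]] - 1.5 * ballW
  wHi <- (edges[["lead"]] + edges[["stop"]]) / 2
  win <- which(pos >= wLo & pos <= wHi)
  ssd <- function(d) {
    sh <- approx(refProf@positions, refAtt, pos + d * M, rule = 2)$y
    n <- length(sh)
    tmpl <- c(0, cumsum((sh[-1] + sh[-n]) / 2)) * pitch
    tmpl <- tmpl / max(tmpl)
    sum((tmpl[win] - trAtt[win] / plat)^2)
  }
  fine <- seq(m@deltaX - 0.5, m@deltaX + 0.5, by = 0.01 * pitch / M)
  brute <- fine[which.min(vapply(fine, ssd, numeric(1)))]
  expect_close(m@deltaX, brute, 0.05 * pitch / M)
})

test_that("beam-off search range must bracket the minimum", {
  p <- beamOffPair(97.69)
  expect_error(beamOffDelay(p$reference, p$trace, p$geometry, 24,
                            search = c(0, 0.5)), "search")
})

test_that("end-to-end recovery holds across the delay range, both phases", {
  tolMs <- pixelEquivalentMs()
  for (d in c(50, 150, 500)) {
    pOn <- beamOnPair(d)
    expect_close(
      delayMs(beamOnDelay(pOn$reference, pOn$motion, pOn$geometry, 24)),
      d, tolMs, label = sprintf("beam-on %g ms", d))
    pOff <- beamOffPair(d)
    expect_close(
      delayMs(beamOffDelay(pOff$reference, pOff$trace, pOff$geometry, 24)),
      d, tolMs, label = sprintf("beam-off %g ms", d))
  }
})
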