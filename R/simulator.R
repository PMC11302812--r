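#' Construct a ball specification
#'
#' @param diameter physical ball diameter in mm at the isocenter plane
#'   (default 6; a package default, configurable to match the phantom at
#'   hand).
#' @param contrast fractional attenuation at full ball coverage, in (0, 1]
#'   (default 0.5).
#' @param backgroundLevel open-field detector counts (default 40000).
#' @return A [BallSpec-class].
#' @export
BallSpec <- function(diameter = 6, contrast = 0.5, backgroundLevel = 40000) {
  new("BallSpec", diameter = as.numeric(diameter),
      contrast = as.numeric(contrast),
      backgroundLevel = as.numeric(backgroundLevel))
}

#' Construct a simulation scenario
#'
#' @param geometry a [BeamGeometry-class] (default: standard geometry,
#'   SAD 1000 mm, SID 1600 mm, 0.34 mm pitch).
#' @param ball a [BallSpec-class].
#' @param velocity phantom speed in mm/s at the isocenter plane (default 24).
#' @param trueDelay ground-truth delay in ms (default 0).
#' @param phase `"beam_on"` or `"beam_off"`.
#' @param direction `"descending"` (default) or `"ascending"`.
#' @param referencePosition gate reference position in mm, isocenter plane.
#' @param beamDuration beam-on time in s for beam-off traces (default 1).
#' @param rampTime linear dose-rate ramp-down in ms at beam-off (default 0).
#' @param noiseSigma additive Gaussian noise SD in counts (default 0).
#' @param seed RNG seed for the noise draw (default 1).
#' @return A [SimScenario-class].
#' @export
SimScenario <- function(geometry = BeamGeometry(), ball = BallSpec(),
                        velocity = 24, trueDelay = 0, phase = "beam_on",
                        direction = "descending", referencePosition = 0,
                        beamDuration = 1, rampTime = 0, noiseSigma = 0,
                        seed = 1L) {
  new("SimScenario", geometry = geometry, ball = ball,
      velocity = as.numeric(velocity), trueDelay = as.numeric(trueDelay),
      phase = match.arg(phase, c("beam_on", "beam_off")),
      direction = match.arg(direction, c("descending", "ascending")),
      referencePosition = as.numeric(referencePosition),
      beamDuration = as.numeric(beamDuration),
      rampTime = as.numeric(rampTime), noiseSigma = as.numeric(noiseSigma),
      seed = as.integer(seed))
}

## area-weighted coverage of a disk over the pixel grid; cx, cy in det mm
## (motion axis = x = columns), R in det mm. Interior/exterior pixels are
## decided by center distance; edge pixels are subsampled nsub x nsub.
.diskCoverage <- function(rowPos, colPos, cx, cy, R, pitch, nsub = 16L) {
  nr <- length(rowPos); nc <- length(colPos)
  dx2 <- (colPos - cx)^2
  dy2 <- (rowPos - cy)^2
  D <- sqrt(outer(dy2, dx2, `+`))
  cov <- matrix(0, nr, nc)
  half <- pitch * sqrt(2) / 2
  cov[D <= R - half] <- 1
  edge <- which(D > R - half & D < R + half, arr.ind = TRUE)
  if (nrow(edge)) {
    off <- ((seq_len(nsub) - 0.5) / nsub - 0.5) * pitch
    R2 <- R^2
    for (k in seq_len(nrow(edge))) {
      i <- edge[k, 1L]; j <- edge[k, 2L]
      sy <- rowPos[i] + off - cy
      sx <- colPos[j] + off - cx
      cov[i, j] <- mean(outer(sy^2, sx^2, `+`) <= R2)
    }
  }
  cov
}

.gridPositions <- function(geometry) {
  shp <- geometry@imageShape
  pitch <- geometry@pixelPitch
  list(row = (seq_len(shp[1L]) - (shp[1L] + 1) / 2) * pitch,
       col = (seq_len(shp[2L]) - (shp[2L] + 1) / 2) * pitch)
}

.addNoise <- function(mat, sigma, seed) {
  if (sigma > 0) {
    mat <- mat + withr::with_seed(seed,
      stats::rnorm(length(mat), 0, sigma))
    mat[mat < 0] <- 0
  }
  mat
}

.checkInside <- function(lo, hi, colPos, what) {
  if (lo < min(colPos) || hi > max(colPos))
    stop(what, " footprint extends outside the image (",
         sprintf("%.1f..%.1f mm vs %.1f..%.1f mm", lo, hi,
                 min(colPos), max(colPos)), ")")
}

## render an opaque-disk ball centered at isocenter position `posIso` (mm)
.renderBallImage <- function(scenario, posIso) {
  g <- scenario@geometry
  M <- magnification(g)
  gp <- .gridPositions(g)
  R <- scenario@ball@diameter / 2 * M
  cx <- posIso * M
  .checkInside(cx - R, cx + R, gp$col, "ball")
  cov <- .diskCoverage(gp$row, gp$col, cx, 0, R, g@pixelPitch)
  bg <- scenario@ball@backgroundLevel
  img <- bg * (1 - scenario@ball@contrast * cov)
  img <- .addNoise(img, scenario@noiseSigma, scenario@seed)
  PortalImage(img, pixelPitch = g@pixelPitch, motionAxis = "cols")
}

#' Render a static reference portal image
#'
#' Draws the magnified ball footprint (an antialiased opaque disk) at the
#' scenario's reference position on a uniform background, then adds seeded
#' Gaussian noise. Positions are isocenter-plane mm; the footprint is
#' placed at `referencePosition * magnification` on the detector, measured
#' from the image center along the motion axis (columns).
#'
#' @param scenario a [SimScenario-class].
#' @return A [PortalImage-class].
#' @export
renderReference <- function(scenario) {
  stopifnot(is(scenario, "SimScenario"))
  .renderBallImage(scenario, scenario@referencePosition)
}

#' Render a beam-on snapshot
#'
#' The beam-on image is a near-instantaneous low-MU exposure taken when
#' radiation actually starts, i.e. `trueDelay` ms after the phantom crossed
#' the beam-on reference position. The ball therefore sits
#' `velocity * trueDelay / 1000` mm beyond the reference position along the
#' motion direction.
#'
#' @param scenario a [SimScenario-class] with `phase = "beam_on"`.
#' @return A [PortalImage-class].
#' @export
renderBeamOnSnapshot <- function(scenario) {
  stopifnot(is(scenario, "SimScenario"))
  if (scenario@phase != "beam_on")
    stop("scenario phase must be \"beam_on\"")
  s <- .dirSign(scenario@direction)
  pos <- scenario@referencePosition +
    s * scenario@velocity * scenario@trueDelay / 1000
  .renderBallImage(scenario, pos)
}

#' Render a beam-off blur trace
#'
#' The beam-off image integrates the moving ball over the whole beam-on
#' interval, producing an elongated (elliptical) blur trace. The ball's
#' final position is `velocity * trueDelay / 1000` mm beyond the beam-off
#' reference position along the motion direction; the exposure covers
#' `beamDuration` seconds of travel ending there. Each pixel's attenuation
#' is proportional to the time the disk covered it (closed form per row:
#' the overlap of the chord interval with the travel interval), scaled so
#' the central plateau depth equals `contrast * backgroundLevel` — the same
#' depth as the static ball — since the analysis normalises profiles to
#' unit plateau anyway. If `rampTime > 0` the beam intensity decays
#' linearly to zero over the final `rampTime` ms of travel.
#'
#' @param scenario a [SimScenario-class] with `phase = "beam_off"`.
#' @return A [PortalImage-class].
#' @export
renderBeamOffTrace <- function(scenario) {
  stopifnot(is(scenario, "SimScenario"))
  if (scenario@phase != "beam_off")
    stop("scenario phase must be \"beam_off\"")
  g <- scenario@geometry
  M <- magnification(g)
  gp <- .gridPositions(g)
  pitch <- g@pixelPitch
  R <- scenario@ball@diameter / 2 * M
  s <- .dirSign(scenario@direction)
  stopIso <- scenario@referencePosition +
    s * scenario@velocity * scenario@trueDelay / 1000
  startIso <- stopIso - s * scenario@velocity * scenario@beamDuration
  stopDet <- stopIso * M
  startDet <- startIso * M
  lo <- min(startDet, stopDet); hi <- max(startDet, stopDet)
  .checkInside(lo - R, hi + R, gp$col, "trace")

  ## weight along the travel path: 1, decaying linearly to 0 over the final
  ## rampDet mm before the stop (detector-plane path coordinate)
  rampDet <- scenario@velocity * scenario@rampTime / 1000 * M
  ## antiderivative of the weight, taken along the motion direction
  ## from the start; express in absolute det coordinate p in [lo, hi]
  W <- function(p) {
    # integral of weight from start to p (measured along motion direction)
    trav <- if (s > 0) p - startDet else startDet - p
    trav <- pmin(pmax(trav, 0), hi - lo)
    total <- hi - lo
    if (rampDet <= 0) return(trav)
    flat <- max(total - rampDet, 0)
    r <- min(rampDet, total)
    ifelse(trav <= flat, trav,
           flat + (trav - flat) - (trav - flat)^2 / (2 * r))
  }
  covInt <- function(a, b) {  # integral of weight over [a,b] along motion dir
    if (s > 0) W(b) - W(a) else W(a) - W(b)
  }

  bg <- scenario@ball@backgroundLevel
  img <- matrix(bg, length(gp$row), length(gp$col))
  depthScale <- scenario@ball@contrast * bg / (2 * R)
  for (i in seq_along(gp$row)) {
    dy <- gp$row[i]
    if (abs(dy) >= R) next
    ch <- sqrt(R^2 - dy^2)
    a <- pmax(gp$col - ch, lo)
    b <- pmin(gp$col + ch, hi)
    ov <- ifelse(b > a, covInt(a, b), 0)
    img[i, ] <- bg - depthScale * ov
  }
  img <- .addNoise(img, scenario@noiseSigma, scenario@seed)
  PortalImage(img, pixelPitch = pitch, motionAxis = "cols")
}

#' Simulate a full QA acquisition run on disk
#'
#' Writes reference and motion images (16-bit TIFF), a manifest CSV
#' (`path,role,beam_mode,repeat`) consumable by [runEndToEnd()], and a
#' ground-truth JSON sidecar recording the scenario parameters.
#'
#' @param outDir output directory (created if missing).
#' @param phase `"beam_on"` or `"beam_off"`.
#' @param delaysMs named numeric vector: ground-truth delay per beam-mode
#'   label, e.g. `c("6xFFF, 1200" = 300)`.
#' @param nRepeats repeats per beam mode (default 5).
#' @param gate a [GateConfig-class]; its reference positions and direction
#'   drive the renderer (default: center 1 mm, halfwidth 1 mm, descending).
#' @param geometry a [BeamGeometry-class].
#' @param ball a [BallSpec-class].
#' @param velocity phantom speed in mm/s (default 24).
#' @param noiseSigma Gaussian noise SD in counts (default 0).
#' @param beamDuration beam-on seconds for beam-off traces (default 1).
#' @param seed base RNG seed; per-image seeds are derived from it.
#' @return Invisibly, the manifest path.
#' @export
simulateRun <- function(outDir, phase, delaysMs, nRepeats = 5,
                        gate = GateConfig(), geometry = BeamGeometry(),
                        ball = BallSpec(), velocity = 24, noiseSigma = 0,
                        beamDuration = 1, seed = 1L) {
  phase <- match.arg(phase, c("beam_on", "beam_off"))
  stopifnot(length(delaysMs) >= 1L, !is.null(names(delaysMs)))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  refPos <- gateReferencePositions(gate)[[
    if (phase == "beam_on") "beamOn" else "beamOff"]]
  rows <- list()
  seed <- as.integer(seed)
  k <- 0L
  for (m in seq_along(delaysMs)) {
    mode <- names(delaysMs)[m]
    safe <- gsub("[^A-Za-z0-9]+", "_", mode)
    for (r in seq_len(nRepeats)) {
      k <- k + 1L
      sc <- SimScenario(geometry = geometry, ball = ball,
                        velocity = velocity, trueDelay = delaysMs[[m]],
                        phase = phase, direction = gate@direction,
                        referencePosition = refPos,
                        beamDuration = beamDuration,
                        noiseSigma = noiseSigma,
                        seed = (seed + 7L * k) %% .Machine$integer.max)
      ref <- renderReference(
        SimScenario(geometry = geometry, ball = ball, velocity = velocity,
                    phase = phase, direction = gate@direction,
                    referencePosition = refPos,
                    beamDuration = beamDuration, noiseSigma = noiseSigma,
                    seed = (seed + 7L * k + 3L) %% .Machine$integer.max))
      mot <- if (phase == "beam_on") renderBeamOnSnapshot(sc)
             else renderBeamOffTrace(sc)
      refPath <- file.path(outDir, sprintf("%s_rep%d_reference.tif", safe, r))
      motPath <- file.path(outDir, sprintf("%s_rep%d_%s.tif", safe, r,
        if (phase == "beam_on") "motion" else "trace"))
      writePortalImage(ref, refPath)
      writePortalImage(mot, motPath)
      rows[[length(rows) + 1L]] <- data.frame(
        path = basename(refPath), role = "reference", beam_mode = mode,
        repeat. = r, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        path = basename(motPath),
        role = if (phase == "beam_on") "motion" else "trace",
        beam_mode = mode, repeat. = r, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  names(manifest)[names(manifest) == "repeat."] <- "repeat"
  manifestPath <- file.path(outDir, "manifest.csv")
  utils::write.csv(manifest, manifestPath, row.names = FALSE)
  truth <- list(phase = phase, true_delay_ms = as.list(delaysMs),
                velocity_mm_s = velocity, seed = seed,
                n_repeats = nRepeats, noise_sigma = noiseSigma,
                geometry = list(sad_mm = geometry@sad, sid_mm = geometry@sid,
                                pixel_pitch_mm = geometry@pixelPitch),
                gate = list(center_mm = gate@center,
                            halfwidth_mm = gate@halfwidth,
                            direction = gate@direction))
  jsonlite::write_json(truth, file.path(outDir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifestPath)
}
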