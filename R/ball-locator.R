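## Robust background estimate for a profile (or any vector of counts):
## take an upper-quartile first guess, mask everything attenuated by more
## than 20% of the apparent depth, and use the median of the rest. Works
## even when the trace covers half of the profile, where a plain median
## would be contaminated.
.estimateBackground <- function(v) {
  b0 <- stats::quantile(v, 0.75, names = FALSE)
  a0 <- b0 - v
  top <- max(a0)
  if (top <= 0) return(stats::median(v))
  stats::median(v[a0 <= 0.2 * top])
}

## contiguous runs of TRUE, as a list of index vectors
.runs <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  split(idx, cumsum(c(1L, diff(idx) != 1L)))
}

## linearly interpolated crossings of `att` through `level`;
## returns all upward/downward crossing positions in mm
.crossings <- function(pos, att, level) {
  above <- att >= level
  ch <- which(diff(above) != 0L)
  vapply(ch, function(i) {
    pos[i] + (level - att[i]) / (att[i + 1L] - att[i]) * (pos[i + 1L] - pos[i])
  }, numeric(1))
}

#' Extract a motion-axis intensity profile
#'
#' Locates the ball's transverse coordinate as the minimum of the
#' transverse (per-row, for motion along columns) means, then averages the
#' image over a transverse band of `bandHalfwidth` pixels either side and
#' returns the band mean against detector-plane position (mm, origin at
#' the image center).
#'
#' @param image a [PortalImage-class].
#' @param bandHalfwidth transverse averaging half-width in pixels; `NULL`
#'   (default) picks the ball radius, estimated as half the transverse
#'   FWHM of the attenuation through the ball.
#' @return A [Profile-class].
#' @export
extractProfile <- function(image, bandHalfwidth = NULL) {
  stopifnot(is(image, "PortalImage"))
  px <- if (image@motionAxis == "cols") image@pixels else t(image@pixels)
  transMeans <- rowMeans(px)
  r0 <- which.min(transMeans)
  if (is.null(bandHalfwidth)) {
    ## half the transverse FWHM of the attenuation (== ball radius in px)
    tbg <- .estimateBackground(transMeans)
    tatt <- tbg - transMeans
    d <- max(tatt)
    h <- if (d > 0) {
      cr <- .crossings(seq_along(transMeans), tatt, d / 2)
      if (length(cr) >= 2L) max(1L, floor((max(cr) - min(cr)) / 2)) else 1L
    } else 0L
    bandHalfwidth <- h
  }
  bandHalfwidth <- as.integer(bandHalfwidth)
  if (2L * bandHalfwidth + 1L > nrow(px))
    stop("averaging band extends outside the image")
  # keep the band inside the image (matters only for structureless images,
  # where the transverse minimum is arbitrary)
  r0 <- min(max(r0, 1L + bandHalfwidth), nrow(px) - bandHalfwidth)
  lo <- r0 - bandHalfwidth; hi <- r0 + bandHalfwidth
  n <- ncol(px)
  new("Profile",
      positions = (seq_len(n) - (n + 1) / 2) * image@pixelPitch,
      intensities = colMeans(px[lo:hi, , drop = FALSE]),
      bandHalfwidth = bandHalfwidth)
}

#' Locate the ball center with sub-pixel precision
#'
#' Works on the band-averaged motion-axis profile: the attenuation
#' (background minus intensity) is thresholded at 50% of its maximum
#' depth, and the center is the attenuation-weighted centroid of the
#' excess above that threshold over the contiguous region containing the
#' deepest point. Weighting by the excess rather than the raw attenuation
#' makes the boundary pixels enter with near-zero weight, removing the
#' sub-pixel quantisation bias a hard cut would cause.
#'
#' A detection requires the depth to exceed 6 background noise SDs and
#' 2% of the background level; a profile with two or more disjoint
#' above-threshold regions (at least 3 px each) is ambiguous.
#'
#' @param image a [PortalImage-class] containing a single ball footprint.
#' @param bandHalfwidth see [extractProfile()].
#' @return A [BallDetection-class]: center (mm at the detector plane, and
#'   as fractional pixel index), attenuation depth, FWHM (mm) and a
#'   heuristic quality score in [0, 1].
#' @export
locateBallCenter <- function(image, bandHalfwidth = NULL) {
  prof <- extractProfile(image, bandHalfwidth)
  pos <- prof@positions
  intens <- prof@intensities
  bg <- .estimateBackground(intens)
  att <- bg - intens
  depth <- max(att)
  ## background noise estimate away from the ball
  bgMask <- att <= 0.2 * max(depth, 0)
  sigma <- if (sum(bgMask) > 2) stats::sd(att[bgMask]) else 0
  if (depth <= max(6 * sigma, 0.02 * bg))
    stop("no ball found: maximum attenuation does not exceed ",
         "the detection threshold")
  runs <- .runs(att > depth / 2)
  runs <- runs[vapply(runs, length, integer(1)) >= 3L]
  if (length(runs) > 1L)
    stop("ambiguous detection: ", length(runs),
         " disjoint regions above the 50% threshold")
  if (length(runs) == 0L)
    stop("no ball found: above-threshold region too small")
  reg <- runs[[1L]]
  w <- att[reg] - depth / 2
  center <- sum(pos[reg] * w) / sum(w)
  cr <- .crossings(pos, att, depth / 2)
  fwhm <- if (length(cr) >= 2L) max(cr) - min(cr) else NA_real_
  quality <- if (sigma <= 0) 1 else min(1, depth / (20 * sigma))
  pitch <- pos[2L] - pos[1L]
  n <- length(pos)
  new("BallDetection",
      center = center, centerPx = .mmToPx(center, n, pitch),
      depth = depth, fwhm = fwhm, quality = quality)
}

#' Locate the edges of a beam-off blur trace
#'
#' The trace is the time integral of the moving ball, so along the motion
#' axis each row's attenuation ramps up linearly over one ball width, sits
#' on a plateau, and ramps down; the 50%-of-plateau crossings fall exactly
#' at the ball-center positions at the start and stop of the exposure (for
#' every row, hence also for the band average). The returned edges are
#' therefore the exposure's start ("lead") and stop ball-center positions
#' in mm at the detector plane, found by linear interpolation at the 50%
#' crossing. The stop edge is the one downstream in the motion direction.
#'
#' A warning is issued when the profile has essentially no plateau
#' (travel much shorter than the ball), in which case the crossings are
#' still returned but are biased estimates.
#'
#' @param image a [PortalImage-class] containing an elongated blur trace.
#' @param direction `"descending"` (default) or `"ascending"` phantom
#'   motion.
#' @param bandHalfwidth see [extractProfile()].
#' @return Named numeric vector `c(lead = , stop = )` in mm at the
#'   detector plane.
#' @export
locateTraceEdges <- function(image, direction = "descending",
                             bandHalfwidth = NULL) {
  s <- .dirSign(direction)
  prof <- extractProfile(image, bandHalfwidth)
  pos <- prof@positions
  att <- .estimateBackground(prof@intensities) - prof@intensities
  depth <- max(att)
  if (depth <= 0) stop("no trace found: profile is flat")
  plateau <- stats::median(att[att > 0.8 * depth])
  w50 <- .crossings(pos, att, plateau / 2)
  if (length(w50) < 2L)
    stop("no trace edges found at the 50% level")
  lo <- min(w50); hi <- max(w50)
  w90 <- .crossings(pos, att, 0.9 * plateau)
  plateauLen <- if (length(w90) >= 2L) max(w90) - min(w90) else 0
  if (plateauLen < 0.6 * (hi - lo))
    warning("degenerate trace: profile has essentially no plateau; ",
            "edge positions may be biased")
  if (s > 0) c(lead = lo, stop = hi) else c(lead = hi, stop = lo)
}
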