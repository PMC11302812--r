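#' Read a phantom motion waveform from CSV
#'
#' The file must have a header with columns `time_s` and `position_mm`
#' (decimal point, UTF-8). Times must be strictly increasing and positions
#' finite.
#'
#' @param path path to the CSV file.
#' @return A data.frame with numeric columns `time_s`, `position_mm`.
#' @export
readWaveform <- function(path) {
  wf <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "position_mm") %in% names(wf)))
    stop("waveform CSV must have columns 'time_s' and 'position_mm'")
  wf <- wf[, c("time_s", "position_mm")]
  validateWaveform(wf)
  wf
}

#' @keywords internal
validateWaveform <- function(wf) {
  if (!is.numeric(wf$time_s) || !is.numeric(wf$position_mm))
    stop("waveform columns must be numeric")
  if (any(!is.finite(wf$time_s)) || any(!is.finite(wf$position_mm)))
    stop("waveform contains non-finite values")
  if (any(diff(wf$time_s) <= 0))
    stop("waveform times must be strictly increasing")
  invisible(wf)
}

#' Fit the phantom traversal velocity over a time window
#'
#' Ordinary least-squares line through (time, position) restricted to the
#' stated window. The phantom is driven so that the gate-crossing segment
#' of the waveform is linear; the window selects that segment explicitly
#' (no automatic segmentation is attempted). The p-value is the two-sided
#' t-test on the slope with n - 2 residual degrees of freedom; with exactly
#' two points the line is exact and the p-value is NA.
#'
#' @param waveform data.frame with columns `time_s`, `position_mm`
#'   (see [readWaveform()]).
#' @param window numeric length-2, inclusive time window in seconds
#'   (default: the full waveform).
#' @return A [VelocityFit-class] with the absolute speed (mm/s), signed
#'   slope, intercept, R-squared, slope p-value and the number of points
#'   used.
#' @examples
#' wf <- data.frame(time_s = c(0, 0.5, 1), position_mm = c(20, 8, -4))
#' fitVelocity(wf)  # speed 24 mm/s, R-squared 1
#' @export
fitVelocity <- function(waveform, window = range(waveform$time_s)) {
  validateWaveform(waveform)
  stopifnot(length(window) == 2L, all(is.finite(window)))
  keep <- waveform$time_s >= min(window) & waveform$time_s <= max(window)
  t <- waveform$time_s[keep]
  p <- waveform$position_mm[keep]
  n <- length(t)
  if (n < 2L)
    stop("fewer than 2 waveform samples inside the fit window")
  if (diff(range(t)) == 0)
    stop("degenerate fit: zero time variance inside the window")
  fit <- stats::lm(p ~ t)
  # noise-free waveforms fit exactly; summary.lm's perfect-fit caveat is
  # expected there, not a data problem
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- if (stats::var(p) == 0) 1 else sm$r.squared
  pval <- if (n > 2L) unname(sm$coefficients[2L, 4L]) else NA_real_
  new("VelocityFit",
      speed = abs(slope), signedSlope = slope, intercept = intercept,
      rSquared = min(max(r2, 0), 1), pValue = pval, nPoints = as.integer(n))
}

#' Construct a gating-window configuration
#'
#' @param center gate center level in mm.
#' @param halfwidth gate halfwidth in mm (default 1).
#' @param direction `"descending"` (default) or `"ascending"` phantom
#'   motion through the gate.
#' @return A [GateConfig-class].
#' @export
GateConfig <- function(center = 1, halfwidth = 1, direction = "descending") {
  new("GateConfig", center = as.numeric(center),
      halfwidth = as.numeric(halfwidth),
      direction = match.arg(direction, c("descending", "ascending")))
}

#' Gate reference positions for beam-on and beam-off
#'
#' The beam turns on when the phantom enters the gating window and off when
#' it leaves, so the beam-on reference is the entry boundary and the
#' beam-off reference the exit boundary. For a phantom descending through
#' the gate the entry boundary is `center + halfwidth` and the exit
#' boundary `center - halfwidth`; ascending motion mirrors this.
#'
#' @param gate a [GateConfig-class].
#' @return Named numeric vector `c(beamOn = , beamOff = )` in mm.
#' @examples
#' gateReferencePositions(GateConfig(center = 1, halfwidth = 1))
#' # beamOn 2, beamOff 0 for a descending phantom
#' @export
gateReferencePositions <- function(gate) {
  stopifnot(is(gate, "GateConfig"))
  s <- .dirSign(gate@direction)
  c(beamOn = gate@center - s * gate@halfwidth,
    beamOff = gate@center + s * gate@halfwidth)
}
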