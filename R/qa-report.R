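#' Aggregate repeated measurements for one beam mode
#'
#' Computes the mean distance discrepancy (MDD, the mean isocenter-plane
#' displacement over repeats), the mean delay, and the sample standard
#' deviation (divisor n - 1) of the delay over repeats — the convention
#' for repeated measurements of the same quantity. A single repeat yields
#' sd = 0 with a warning.
#'
#' @param measurements list of [DelayMeasurement-class] sharing beam mode,
#'   phase and velocity.
#' @return A [BeamModeResult-class].
#' @examples
#' ms <- lapply(c(95, 100, 105, 100, 100), function(d)
#'   new("DelayMeasurement", deltaX = d * 24 / 1000, velocity = 24,
#'       delay = d, phase = "beam_on", repeatIndex = 1L,
#'       beamMode = "6x, 600", diagnostics = list()))
#' aggregateRepeats(ms)  # mean 100 ms, sd 3.54 ms
#' @export
aggregateRepeats <- function(measurements) {
  stopifnot(is.list(measurements), length(measurements) >= 1L,
            all(vapply(measurements, is, logical(1), "DelayMeasurement")))
  modes <- unique(vapply(measurements, function(m) m@beamMode, character(1)))
  phases <- unique(vapply(measurements, function(m) m@phase, character(1)))
  vels <- unique(vapply(measurements, function(m) m@velocity, numeric(1)))
  if (length(modes) > 1L)
    stop("mixed beam modes in one aggregation: ",
         paste(modes, collapse = ", "))
  if (length(phases) > 1L)
    stop("mixed phases in one aggregation")
  if (length(vels) > 1L)
    stop("mixed velocities in one aggregation")
  delays <- vapply(measurements, function(m) m@delay, numeric(1))
  dxs <- vapply(measurements, function(m) m@deltaX, numeric(1))
  n <- length(delays)
  if (n == 1L) {
    warning("single repeat: sd reported as 0")
    sdDelay <- 0
  } else {
    sdDelay <- stats::sd(delays)
  }
  new("BeamModeResult",
      beamMode = modes, phase = phases, mdd = mean(dxs),
      meanDelay = mean(delays), sd = sdDelay, nRepeats = as.integer(n),
      velocity = vels)
}

## population standard deviation (divisor N)
.popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Cross-energy summary for one system and phase
#'
#' The per-beam-mode mean delays are averaged arithmetically and their
#' spread reported as the population standard deviation (divisor N): the
#' modes are the complete set of conditions tested, not a sample from a
#' larger population.
#'
#' @param results list of [BeamModeResult-class] sharing phase.
#' @param system system label (e.g. `"Catalyst"`).
#' @return A [SystemSummary-class]. Values are stored at full precision;
#'   display and reports round to 2 decimals.
#' @examples
#' ## from per-mode mean delays alone:
#' summarizeSystemMeans(c(297.08, 302.50, 305.42, 308.75),
#'                      system = "Catalyst", phase = "beam_on")
#' @export
summarizeSystem <- function(results, system = "") {
  stopifnot(is.list(results), length(results) >= 1L,
            all(vapply(results, is, logical(1), "BeamModeResult")))
  phases <- unique(vapply(results, function(r) r@phase, character(1)))
  if (length(phases) > 1L)
    stop("mixed phases in one system summary")
  means <- vapply(results, function(r) r@meanDelay, numeric(1))
  modes <- vapply(results, function(r) r@beamMode, character(1))
  new("SystemSummary", system = system, phase = phases,
      mean = mean(means), sd = .popSd(means), modesIncluded = modes)
}

#' @rdname summarizeSystem
#' @param meanDelays numeric vector of per-mode mean delays in ms.
#' @param phase phase label for the summary.
#' @param modes optional beam-mode labels.
#' @export
summarizeSystemMeans <- function(meanDelays, system = "", phase = "beam_on",
                                 modes = names(meanDelays)) {
  stopifnot(length(meanDelays) >= 1L, all(is.finite(meanDelays)))
  if (is.null(modes)) modes <- as.character(seq_along(meanDelays))
  new("SystemSummary", system = system, phase = phase,
      mean = mean(meanDelays), sd = .popSd(meanDelays),
      modesIncluded = modes)
}

#' Check a summary against an action level
#'
#' @param summary a [SystemSummary-class].
#' @param threshold action level in ms (> 0, from configuration).
#' @return A [ToleranceCheck-class]; passes iff the summary mean is <=
#'   the threshold (inclusive).
#' @export
checkTolerance <- function(summary, threshold) {
  stopifnot(is(summary, "SystemSummary"),
            isTRUE(is.finite(threshold)), threshold > 0)
  new("ToleranceCheck", threshold = threshold, measured = summary@mean,
      pass = summary@mean <= threshold)
}

#' Write / read a QA report CSV
#'
#' Columns `system,phase,beam_mode,n_repeats,mdd_mm,mean_delay_ms,sd_ms`;
#' numeric columns are printed at 2 decimals (mm and ms), and reading the
#' file back reproduces them bit-exactly at that precision.
#'
#' @param results list of [BeamModeResult-class].
#' @param path output CSV path.
#' @param system system label written on every row.
#' @return `writeReportCsv` invisibly returns the data.frame written;
#'   `readReportCsv` returns the data.frame read.
#' @export
writeReportCsv <- function(results, path, system = "") {
  stopifnot(all(vapply(results, is, logical(1), "BeamModeResult")))
  df <- data.frame(
    system = system,
    phase = vapply(results, function(r) r@phase, character(1)),
    beam_mode = vapply(results, function(r) r@beamMode, character(1)),
    n_repeats = vapply(results, function(r) r@nRepeats, integer(1)),
    mdd_mm = sprintf("%.2f", vapply(results, function(r) r@mdd, numeric(1))),
    mean_delay_ms = sprintf("%.2f",
      vapply(results, function(r) r@meanDelay, numeric(1))),
    sd_ms = sprintf("%.2f", vapply(results, function(r) r@sd, numeric(1))),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(df)
}

#' @rdname writeReportCsv
#' @export
readReportCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("system", "phase", "beam_mode", "n_repeats", "mdd_mm",
            "mean_delay_ms", "sd_ms")
  if (!all(need %in% names(df)))
    stop("not a QA report CSV: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (col in c("mdd_mm", "mean_delay_ms", "sd_ms"))
    df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write a system summary as JSON
#'
#' @param summary a [SystemSummary-class].
#' @param path output JSON path.
#' @param tolerance optional action level in ms; when given, a
#'   [checkTolerance()] block is embedded.
#' @return Invisibly, the list serialised.
#' @export
writeSummaryJson <- function(summary, path, tolerance = NULL) {
  stopifnot(is(summary, "SystemSummary"))
  out <- list(system = summary@system, phase = summary@phase,
              mean_ms = round(summary@mean, 2),
              sd_ms = round(summary@sd, 2),
              sd_convention = "population (divisor N) across mode means",
              modes_included = summary@modesIncluded)
  if (!is.null(tolerance)) {
    chk <- checkTolerance(summary, tolerance)
    out$tolerance <- list(threshold_ms = chk@threshold, pass = chk@pass)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
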