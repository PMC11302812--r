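#' Bundled reference latency measurements
#'
#' Per-beam-mode mean distance discrepancies (MDD, mm) and mean delays
#' (ms) measured with this QA method on three commercial respiratory
#' gating configurations (a Catalyst system and two AlignRT versions),
#' at a phantom speed of 24 mm/s with five repeats per mode. Useful as a
#' worked example for the aggregation machinery and as reference levels
#' when commissioning the method.
#'
#' @param system optional filter, e.g. `"Catalyst"`.
#' @param phase optional filter, `"beam_on"` or `"beam_off"`.
#' @return data.frame with columns `system`, `phase`, `beam_mode`,
#'   `mdd_mm`, `mean_delay_ms`, `sd_ms`.
#' @examples
#' cat1 <- publishedDelays("Catalyst", "beam_on")
#' summarizeSystemMeans(cat1$mean_delay_ms, "Catalyst", "beam_on")
#' @export
publishedDelays <- function(system = NULL, phase = NULL) {
  path <- system.file("extdata", "published_beam_delays.csv",
                      package = "gatelag", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(system)) df <- df[df$system == system, ]
  if (!is.null(phase)) df <- df[df$phase == phase, ]
  df
}
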