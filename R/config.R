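.configDefaults <- function() {
  list(
    geometry = list(sad_mm = 1000, sid_mm = 1600, pixel_pitch_mm = 0.34),
    gate = list(center_mm = 1, halfwidth_mm = 1, direction = "descending"),
    velocity_mm_s = 24,
    system_label = "",
    beam_mode = "",
    seed = NULL,
    log_level = "info"
  )
}

## merge user values over defaults, erroring on unknown keys with the
## full key path so typos (e.g. gate.widht) are caught, not ignored
.mergeConfig <- function(defaults, user, prefix = "") {
  for (key in names(user)) {
    path <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown config key '", path, "'")
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        stop("config key '", path, "' must be a mapping")
      defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]], path)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' YAML file with keys `geometry` (`sad_mm`, `sid_mm`, `pixel_pitch_mm`),
#' `gate` (`center_mm`, `halfwidth_mm`, `direction`), `velocity_mm_s`,
#' `system_label`, `beam_mode`, `seed` and `log_level`. Missing keys take
#' the standard defaults (SAD 1000 mm, SID 1600 mm, pitch 0.34 mm, gate
#' halfwidth 1 mm, velocity 24 mm/s); unknown keys raise an error naming
#' the key path.
#'
#' @param path YAML config path, or `NULL` for pure defaults.
#' @return A validated list with elements `geometry` ([BeamGeometry-class]),
#'   `gate` ([GateConfig-class]), `velocity`, `systemLabel`, `beamMode`,
#'   `seed`, `logLevel`.
#' @export
loadConfig <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  cfg <- .mergeConfig(.configDefaults(), user)
  if (!isTRUE(is.finite(cfg$velocity_mm_s)) || cfg$velocity_mm_s <= 0)
    stop("config key 'velocity_mm_s' must be positive")
  geom <- BeamGeometry(sad = cfg$geometry$sad_mm, sid = cfg$geometry$sid_mm,
                       pixelPitch = cfg$geometry$pixel_pitch_mm)
  gate <- GateConfig(center = cfg$gate$center_mm,
                     halfwidth = cfg$gate$halfwidth_mm,
                     direction = cfg$gate$direction)
  list(geometry = geom, gate = gate, velocity = cfg$velocity_mm_s,
       systemLabel = cfg$system_label, beamMode = cfg$beam_mode,
       seed = cfg$seed, logLevel = cfg$log_level)
}
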