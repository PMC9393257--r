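#' Default simulation configuration
#'
#' Returns the nested list of parameters that defines the study conditions.
#' Any element can be overridden by name, e.g.
#' `cm_config(noise = list(snr_a_db = 6))` changes one key and keeps the rest.
#'
#' Groups and defaults:
#' \describe{
#'   \item{world}{`n_steps` (250 steps per trial), `arena` (width, depth in
#'     m; the target spawns at the right edge), `target_start` (m),
#'     `spawn_jitter` (the spawn point is drawn uniformly within this many m
#'     of `target_start` along the edge, per trial), `speed_scale` (m of
#'     arena displacement per schedule speed unit per step; schedule speeds
#'     stay on the 0--10 / 0--4 scale).}
#'   \item{acoustics}{`f` tone frequency (Hz), `d` sensor separation (m),
#'     `c` speed of sound (m/s), `amplitude` (peak amplitude), `sample_rate`
#'     (samples/s), `window` (samples per time step).}
#'   \item{auditory}{`backend` ("filter" or "surrogate"), `calib`
#'     ("auto" or a positive dB value), `passband` (Hz), `order`
#'     (per-edge Butterworth order; 2 gives a 4th-order band-pass),
#'     `contra_gain`, `contra_delay` (samples).}
#'   \item{visual}{`width_deg` (57), `depth_m` (4).}
#'   \item{noise}{`snr_a_db`, `snr_v_db` (dB), `ref_power` (reference power
#'     for cue-level noise, mean square of a unit-amplitude carrier).}
#'   \item{agent}{`l_m` wheel separation (0.16 m), `dt` (1 time step),
#'     `motor_gain` (wheel speed in m per time step per unit fused output).}
#'   \item{learning}{`mu` (0.09), `w_init` (c(0.1, 0.1)), `enabled`.}
#' }
#'
#' @param ... named groups of overrides (partial lists are merged).
#' @return a list of class `cm_config`.
#' @export
#' @examples
#' cfg <- cm_config(noise = list(snr_a_db = 6, snr_v_db = 3))
#' cfg$noise$snr_a_db
cm_config <- function(...) {
  base <- list(
    world = list(
      n_steps = 250L,
      arena = c(width = 10, depth = 6),
      target_start = c(x = 5, y = 3),
      spawn_jitter = 0.75,
      speed_scale = 0.005
    ),
    acoustics = list(
      f = 2200, d = 0.013, c = 340,
      amplitude = 1, sample_rate = 44100, window = 44L
    ),
    auditory = list(
      backend = "filter",
      calib = "auto",
      passband = c(1000, 4000),
      order = 2L,
      contra_gain = 0.9,
      contra_delay = 8.3
    ),
    visual = list(width_deg = 57, depth_m = 4),
    noise = list(snr_a_db = 3, snr_v_db = 3, ref_power = 0.09),
    agent = list(l_m = 0.16, dt = 1, motor_gain = 0.0125),
    learning = list(mu = 0.09, w_init = c(w_a = 0.1, w_v = 0.1), enabled = TRUE)
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(base))
    if (length(bad))
      stop("unknown config group(s): ", paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(overrides)) {
      base[[nm]] <- utils::modifyList(base[[nm]], as.list(overrides[[nm]]))
    }
  }
  structure(base, class = "cm_config")
}

#' Read a configuration from a YAML file
#'
#' Keys mirror [cm_config()] groups (e.g. `noise: {snr_a_db: 6}`);
#' unspecified keys keep their defaults.
#'
#' @param path path to a YAML file.
#' @return a `cm_config` list.
#' @export
read_cm_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(cm_config, raw)
}

#' @export
print.cm_config <- function(x, ...) {
  cat("<cm_config>\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
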