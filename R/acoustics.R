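#' Interaural phase difference of a tone
#'
#' Phase offset between the two sound sensors for a plane wave arriving from
#' bearing `theta`: `2 * pi * f * d * sin(theta) / c`. The path-length
#' difference between the sensors is `d * sin(theta)`.
#'
#' @param f tone frequency in Hz.
#' @param d sensor separation in m.
#' @param theta sound bearing in radians relative to the frontal axis
#'   (positive to the right).
#' @param c speed of sound in m/s.
#' @return phase difference in radians (positive when the right sensor leads).
#' @export
#' @examples
#' phase_difference(1500, 0.013, pi / 2)  # maximum for a 13 mm separation
phase_difference <- function(f, d, theta, c = 340) {
  stopifnot_scalar(f, "f", positive = TRUE)
  stopifnot_scalar(d, "d", positive = TRUE)
  stopifnot_scalar(c, "c", positive = TRUE)
  2 * pi * f * d * sin(theta) / c
}

#' Tone frequency giving the same peak phase difference at another separation
#'
#' For sensor separation `d_new`, the frequency whose maximum attainable
#' phase difference equals that of the reference pair `(f_ref, d_ref)` is
#' `f_ref * d_ref / d_new`; a wider head buys no extra phase range.
#'
#' @param d_new new sensor separation in m.
#' @param f_ref reference frequency in Hz (default 1500, the frequency of
#'   peak binaural difference response at 13 mm separation).
#' @param d_ref reference separation in m.
#' @return frequency in Hz.
#' @export
equivalent_peak_frequency <- function(d_new, f_ref = 1500, d_ref = 0.013) {
  stopifnot_scalar(d_new, "d_new", positive = TRUE)
  f_ref * d_ref / d_new
}

#' Acoustic wavelength
#'
#' @param f frequency in Hz.
#' @param c speed of sound in m/s.
#' @return wavelength in m.
#' @export
acoustic_wavelength <- function(f, c = 340) {
  stopifnot_scalar(f, "f", positive = TRUE)
  c / f
}

#' Acoustic parameters of the binaural signal
#'
#' @param f tone frequency in Hz (default 2.2 kHz).
#' @param d sensor separation in m (default 13 mm).
#' @param c speed of sound in m/s.
#' @param amplitude peak tone amplitude (arbitrary units).
#' @param sample_rate samples per second.
#' @param window samples per simulation time step; must span at least two
#'   cycles of `f`.
#' @return a list of class `acoustic_params`.
#' @export
acoustic_params <- function(f = 2200, d = 0.013, c = 340, amplitude = 1,
                            sample_rate = 44100, window = 44L) {
  stopifnot_scalar(f, "f", positive = TRUE)
  stopifnot_scalar(d, "d", positive = TRUE)
  stopifnot_scalar(c, "c", positive = TRUE)
  stopifnot_scalar(amplitude, "amplitude", positive = TRUE)
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  window <- as.integer(window)
  if (window < 2 * sample_rate / f)
    stop("`window` must span at least two cycles of `f`", call. = FALSE)
  structure(list(f = f, d = d, c = c, amplitude = amplitude,
                 sample_rate = sample_rate, window = window),
            class = "acoustic_params")
}

# one window of the two clean sinusoids for a given relative bearing (radians)
binaural_window <- function(bearing, params) {
  dphi <- phase_difference(params$f, params$d, bearing, params$c)
  tt <- 2 * pi * params$f * (seq_len(params$window) - 1L) / params$sample_rate
  list(left = params$amplitude * sin(tt - dphi / 2),
       right = params$amplitude * sin(tt + dphi / 2))
}

#' Emit the binaural signal perceived by the agent
#'
#' One time step's pair of equal-amplitude sinusoids whose phase offset
#' encodes the target bearing relative to the agent's frontal axis (the
#' right channel leads when the target is to the right). Returns silence
#' when the target's sound emission is off. Bearings outside the frontal
#' semicircle are clamped to +/-90 degrees and flagged via the `clamped`
#' attribute, with a warning.
#'
#' @param state a [target_state()].
#' @param pose a [pose()].
#' @param params an [acoustic_params()].
#' @return a list of class `binaural_signal` with elements `left`, `right`
#'   (equal-length sample vectors) and `sample_rate`.
#' @export
emit_binaural <- function(state, pose, params = acoustic_params()) {
  bearing <- relative_bearing(pose, state$position)
  clamped <- FALSE
  if (is.finite(bearing) && abs(bearing) > pi / 2) {
    warning("target bearing outside the frontal semicircle; clamped to +/-90 degrees")
    bearing <- sign(bearing) * pi / 2
    clamped <- TRUE
  }
  if (isTRUE(state$sound_on)) {
    w <- binaural_window(bearing, params)
  } else {
    z <- numeric(params$window)
    w <- list(left = z, right = z)
  }
  structure(list(left = w$left, right = w$right,
                 sample_rate = params$sample_rate),
            class = "binaural_signal", clamped = clamped)
}
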