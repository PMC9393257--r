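#' Synaptic weight pair of the multisensory neuron
#'
#' @param w_a auditory weight (default 0.1).
#' @param w_v visual weight (default 0.1).
#' @param mu learning rate (>= 0, default 0.09).
#' @return a list of class `synaptic_weights`.
#' @export
synaptic_weights <- function(w_a = 0.1, w_v = 0.1, mu = 0.09) {
  w_a <- unname(w_a); w_v <- unname(w_v); mu <- unname(mu)
  stopifnot_scalar(w_a, "w_a"); stopifnot_scalar(w_v, "w_v")
  stopifnot_scalar(mu, "mu")
  if (mu < 0) stop("`mu` must be non-negative", call. = FALSE)
  structure(list(w_a = w_a, w_v = w_v, mu = mu), class = "synaptic_weights")
}

#' One time step's sensory frame
#'
#' @param x_a,x_v auditory and visual directional cues.
#' @param dx_a,dx_v their time derivatives (cue units per time step).
#' @param gate_a logical, target emitted sound this step.
#' @param gate_v logical, target inside the visual receptive field this step.
#' @param t step index.
#' @return a list of class `cue_frame`.
#' @export
cue_frame <- function(x_a, x_v, dx_a = 0, dx_v = 0,
                      gate_a = TRUE, gate_v = TRUE, t = 0L) {
  structure(list(x_a = x_a, x_v = x_v, dx_a = dx_a, dx_v = dx_v,
                 gate_a = isTRUE(gate_a), gate_v = isTRUE(gate_v),
                 t = as.integer(t)),
            class = "cue_frame")
}

#' Fused motor output of the multisensory neuron
#'
#' Weighted summation of the two directional cues:
#' `v = w_v * x_v + w_a * x_a`. Pure function; no state is changed.
#'
#' @param w a [synaptic_weights()].
#' @param frame a [cue_frame()] (only `x_a` and `x_v` are used).
#' @return the fused motor output, a numeric scalar.
#' @export
#' @examples
#' fuse_cues(synaptic_weights(0.3, 0.5), cue_frame(x_a = -0.4, x_v = 0.2))
fuse_cues <- function(w, frame) {
  w$w_v * frame$x_v + w$w_a * frame$x_a
}

#' Backward-difference estimate of a cue's time derivative
#'
#' `(curr - prev) / dt`. The first frame of a trial has no predecessor and
#' returns 0 by convention (`prev = NULL`). Note that an onset transition
#' from an exactly zero cue to a nonzero one has a nonzero derivative: zero
#' instantaneous values do not imply zero dynamics.
#'
#' @param prev previous cue value, or `NULL` at the first frame.
#' @param curr current cue value.
#' @param dt time step (> 0).
#' @return the rate of change in cue units per time step.
#' @export
cue_derivative <- function(prev, curr, dt = 1) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  if (is.null(prev)) return(0)
  (curr - prev) / dt
}

#' Gated crossmodal weight update (input-correlation learning)
#'
#' Differential Hebbian updates in which each weight is driven by its own
#' modality's instantaneous cue and the *other* modality's cue derivative:
#' `w_a <- w_a + mu * x_a * dx_v` (applied only while the target emits
#' sound, irrespective of visibility) and `w_v <- w_v + mu * x_v * dx_a`
#' (applied only while the target is inside the visual receptive field).
#' Ungated weights are returned unchanged. No bounds are imposed on the
#' weights.
#'
#' @param w a [synaptic_weights()].
#' @param frame a [cue_frame()].
#' @return the updated [synaptic_weights()].
#' @export
#' @examples
#' w <- synaptic_weights(0.1, 0.1, mu = 0.09)
#' update_weights(w, cue_frame(x_a = 0.5, x_v = 0, dx_v = 0.2, gate_a = TRUE))
update_weights <- function(w, frame) {
  if (frame$gate_a) w$w_a <- w$w_a + w$mu * frame$x_a * frame$dx_v
  if (frame$gate_v) w$w_v <- w$w_v + w$mu * frame$x_v * frame$dx_a
  w
}

#' Normalize a weight pair onto the unit simplex
#'
#' `(w_a, w_v) / (w_a + w_v)`, the normalization commensurable with the
#' normalized cue reliabilities (each weight's share of the summed weights).
#'
#' @param w a [synaptic_weights()] or a numeric pair `(w_a, w_v)`.
#' @return named numeric vector `c(w_a, w_v)` summing to 1.
#' @export
#' @examples
#' normalize_weights(synaptic_weights(0.2, 0.6))
normalize_weights <- function(w) {
  if (inherits(w, "synaptic_weights")) w <- c(w$w_a, w$w_v)
  if (length(w) != 2L || !all(is.finite(w)))
    stop("`w` must be two finite weights", call. = FALSE)
  s <- sum(w)
  if (s == 0) stop("cannot normalize weights summing to zero", call. = FALSE)
  c(w_a = w[1] / s, w_v = w[2] / s)
}
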