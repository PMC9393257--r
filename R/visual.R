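#' Visual receptive field
#'
#' @param width_deg angular extent in degrees (57 by default, symmetric about
#'   the heading).
#' @param depth_m range limit in m (4 by default).
#' @return a list of class `visual_field`.
#' @export
visual_field <- function(width_deg = 57, depth_m = 4) {
  stopifnot_scalar(width_deg, "width_deg", positive = TRUE)
  stopifnot_scalar(depth_m, "depth_m", positive = TRUE)
  structure(list(width_deg = width_deg, depth_m = depth_m),
            class = "visual_field")
}

#' Bearing of a point relative to the agent's frontal axis
#'
#' @param pose a [pose()].
#' @param position length-2 world coordinates (m).
#' @return bearing in radians wrapped to (-pi, pi], positive when the point
#'   lies to the agent's right.
#' @export
relative_bearing <- function(pose, position) {
  wrap_angle(pose$theta - atan2(position[2] - pose$y, position[1] - pose$x))
}

#' Visual directional cue
#'
#' The target is visible when its head-centered bearing lies within half the
#' field width and its range is within the field depth; the cue is then the
#' bearing mapped one-to-one onto \[-1, +1\] (+1 at the right boundary).
#' Outside the field the cue is exactly zero, modeling a target that is not
#' detected.
#'
#' @param target a [target_state()].
#' @param pose a [pose()].
#' @param field a [visual_field()].
#' @return a list of class `visual_cue` with `x_v` and `visible`.
#' @export
#' @examples
#' p <- pose(0, 0, pi / 2)
#' visual_cue(target_state(c(0, 2)), p)        # dead ahead: 0
visual_cue <- function(target, pose, field = visual_field()) {
  bearing <- relative_bearing(pose, target$position)
  rng <- sqrt(sum((target$position - c(pose$x, pose$y))^2))
  half <- (field$width_deg / 2) * pi / 180
  # 1e-9 rad slack keeps the closed field boundary robust to rounding
  visible <- abs(bearing) <= half + 1e-9 && rng <= field$depth_m + 1e-9
  if (visible) bearing <- clip(bearing, -half, half)
  structure(list(x_v = if (visible) bearing / half else 0,
                 visible = visible),
            class = "visual_cue")
}
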