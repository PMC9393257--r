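#' Agent pose in the planar arena
#'
#' @param x,y position in m.
#' @param theta heading in radians (standard mathematical convention,
#'   counter-clockwise positive), wrapped to (-pi, pi].
#' @return a list of class `pose`.
#' @export
pose <- function(x = 0, y = 0, theta = pi / 2) {
  stopifnot_scalar(x, "x"); stopifnot_scalar(y, "y")
  stopifnot_scalar(theta, "theta")
  structure(list(x = x, y = y, theta = wrap_angle(theta)), class = "pose")
}

#' Differential-drive wheel command
#'
#' @param v_l,v_r signed left/right wheel speeds (m per time step).
#' @param l wheel separation in m (0.16 by default).
#' @return a list of class `wheel_command` with the derived angular velocity
#'   `omega = (v_r - v_l) / l` and, when the wheels differ, the distance `D`
#'   to the instantaneous center of curvature,
#'   `D = (l / 2) * (v_r + v_l) / (v_r - v_l)`.
#' @export
wheel_command <- function(v_l, v_r, l = 0.16) {
  stopifnot_scalar(v_l, "v_l"); stopifnot_scalar(v_r, "v_r")
  stopifnot_scalar(l, "l", positive = TRUE)
  omega <- (v_r - v_l) / l
  D <- if (v_r == v_l) Inf else (l / 2) * (v_r + v_l) / (v_r - v_l)
  structure(list(v_l = v_l, v_r = v_r, l = l, omega = omega, D = D),
            class = "wheel_command")
}

#' Differential-drive forward kinematics
#'
#' Standard instantaneous-center-of-curvature update: equal wheel speeds
#' translate the pose along its heading; opposite speeds rotate it on the
#' spot about the wheel-axle midpoint; in the general case the pose rotates
#' about the ICC (at signed distance `D` along the axle) by `omega * dt`.
#' The translation limit is handled exactly, not as a division by zero.
#'
#' @param p a [pose()].
#' @param cmd a [wheel_command()].
#' @param dt time step (> 0).
#' @return the updated [pose()].
#' @export
#' @examples
#' forward_kinematics(pose(0, 0, 0), wheel_command(1, 1))      # straight line
#' forward_kinematics(pose(0, 0, 0), wheel_command(-0.08, 0.08))  # pure rotation
forward_kinematics <- function(p, cmd, dt = 1) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  if (cmd$v_r == cmd$v_l) {
    v <- cmd$v_l
    return(pose(p$x + v * dt * cos(p$theta),
                p$y + v * dt * sin(p$theta),
                p$theta))
  }
  om <- cmd$omega
  # ICC lies at distance D along the axle (90 degrees to the left of heading)
  icc_x <- p$x - cmd$D * sin(p$theta)
  icc_y <- p$y + cmd$D * cos(p$theta)
  a <- om * dt
  dx <- p$x - icc_x; dy <- p$y - icc_y
  pose(icc_x + cos(a) * dx - sin(a) * dy,
       icc_y + sin(a) * dx + cos(a) * dy,
       p$theta + a)
}

#' Wheel command realizing the reflexive orientation response
#'
#' Maps the fused motor output `v` of the multisensory neuron onto an
#' on-the-spot rotation: both wheels get speed `motor_gain * |v|` with
#' opposite signs, chosen so that a positive fused output (target to the
#' right) rotates the agent clockwise, reducing the bearing error. With the
#' defaults the rotation per step is `2 * motor_gain / l = 0.15625` times
#' `v` radians; the gain is chosen to keep the reflex loop damped (see the
#' package vignette).
#'
#' @param v fused motor output (dimensionless).
#' @param motor_gain wheel speed in m per time step per unit fused output.
#' @param l wheel separation in m.
#' @return a [wheel_command()].
#' @export
command_from_speed <- function(v, motor_gain = 0.0125, l = 0.16) {
  stopifnot_scalar(v, "v")
  wheel_command(v_l = motor_gain * v, v_r = -motor_gain * v, l = l)
}
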