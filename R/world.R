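#' Target state at one time step
#'
#' @param position numeric length-2 position (m).
#' @param sound_on logical, is the target emitting sound this step.
#' @param t non-negative integer time-step index.
#' @return a list of class `target_state`.
#' @export
target_state <- function(position, sound_on = FALSE, t = 0L) {
  position <- as.numeric(position)
  if (length(position) != 2L || !all(is.finite(position)))
    stop("`position` must be two finite coordinates", call. = FALSE)
  t <- as.integer(t)
  if (t < 0L) stop("`t` must be a non-negative integer", call. = FALSE)
  structure(list(position = position, sound_on = isTRUE(sound_on), t = t),
            class = "target_state")
}

#' Generate a random zig-zag trajectory schedule
#'
#' The target's along-track speed is redrawn uniformly on \[0, 10\] schedule
#' units and held for a uniform integer 5--10 steps; the cross-track speed is
#' redrawn uniformly on \[0, 4\] with a random sign and held for a uniform
#' integer 0--5 steps (a zero hold consumes the draw without covering any
#' step). Net motion is right-to-left, i.e. along the direction `(-1, 0)`.
#'
#' @param n_steps number of time steps the schedule must cover (>= 1).
#' @param seed optional integer seed (uses and restores a local RNG state);
#'   with `NULL` the current RNG stream is consumed.
#' @return a list of class `trajectory_schedule` with per-segment tables
#'   `along` (speed, hold) and `cross` (speed, sign, hold), `direction`,
#'   and per-step expansions `along_speed`, `cross_vel` of length `n_steps`.
#' @export
#' @examples
#' tr <- generate_trajectory(100, seed = 7)
#' range(tr$along$speed)
generate_trajectory <- function(n_steps, seed = NULL) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L)
    stop("`n_steps` must be a positive integer", call. = FALSE)
  with_seed(seed, {
    draw_segments <- function(speed_max, hold_min, hold_max, signed) {
      speeds <- numeric(0); holds <- integer(0); signs <- integer(0)
      covered <- 0L
      while (covered < n_steps) {
        s <- runif(1, 0, speed_max)
        h <- sample(hold_min:hold_max, 1L)
        speeds <- c(speeds, s); holds <- c(holds, h)
        if (signed) signs <- c(signs, sample(c(-1L, 1L), 1L))
        covered <- covered + h
      }
      out <- data.frame(speed = speeds, hold = holds)
      if (signed) out$sign <- signs
      out
    }
    along <- draw_segments(10, 5L, 10L, signed = FALSE)
    cross <- draw_segments(4, 0L, 5L, signed = TRUE)
    structure(list(
      along = along,
      cross = cross,
      direction = c(-1, 0),
      along_speed = rep(along$speed, along$hold)[seq_len(n_steps)],
      cross_vel = rep(cross$speed * cross$sign, cross$hold)[seq_len(n_steps)],
      n_steps = n_steps
    ), class = "trajectory_schedule")
  })
}

#' Generate the target's intermittent sound-emission schedule
#'
#' Alternating off/on intervals: off for a uniform integer 5--10 steps, then
#' on for a uniform integer 10--15 steps, repeated until at least `n_steps`
#' are covered. Emission starts in the off state.
#'
#' @inheritParams generate_trajectory
#' @return a list of class `sound_schedule` with `intervals` (data.frame of
#'   off/on durations) and the per-step logical vector `on` (length >=
#'   `n_steps`).
#' @export
#' @examples
#' ss <- sound_duty_schedule(50, seed = 3)
#' mean(ss$on[1:50])
sound_duty_schedule <- function(n_steps, seed = NULL) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L)
    stop("`n_steps` must be a positive integer", call. = FALSE)
  with_seed(seed, {
    offs <- integer(0); ons <- integer(0)
    on <- logical(0)
    while (length(on) < n_steps) {
      o <- sample(5:10, 1L)
      s <- sample(10:15, 1L)
      offs <- c(offs, o); ons <- c(ons, s)
      on <- c(on, rep(FALSE, o), rep(TRUE, s))
    }
    structure(list(intervals = data.frame(off = offs, on = ons), on = on,
                   n_steps = n_steps),
              class = "sound_schedule")
  })
}

#' Advance the target by one time step
#'
#' Applies the along- and cross-track velocities active at `state$t` (scaled
#' by `speed_scale`) and reads the sound gate for the next step from the
#' duty-cycle schedule.
#'
#' @param state a [target_state()].
#' @param schedule a [generate_trajectory()] schedule.
#' @param sound a [sound_duty_schedule()] schedule.
#' @param speed_scale m of displacement per schedule speed unit per step.
#' @return the [target_state()] at `state$t + 1`.
#' @export
step_target <- function(state, schedule, sound, speed_scale = 0.01) {
  t_next <- state$t + 1L
  if (t_next > schedule$n_steps || t_next > length(sound$on))
    stop("time step beyond schedule coverage", call. = FALSE)
  along <- schedule$along_speed[t_next] * speed_scale
  cross <- schedule$cross_vel[t_next] * speed_scale
  dirn <- schedule$direction
  perp <- c(-dirn[2], dirn[1])
  target_state(state$position + along * dirn + cross * perp,
               sound_on = sound$on[t_next], t = t_next)
}

# Vectorized track builder: positions (n_steps+1 x 2, row 1 = start) and
# per-step sound gate. Equivalent to iterating step_target (tested).
target_track <- function(start, schedule, sound, speed_scale = 0.01) {
  start <- unname(as.numeric(start))
  n <- schedule$n_steps
  dirn <- schedule$direction
  perp <- c(-dirn[2], dirn[1])
  dx <- schedule$along_speed * speed_scale * dirn[1] +
    schedule$cross_vel * speed_scale * perp[1]
  dy <- schedule$along_speed * speed_scale * dirn[2] +
    schedule$cross_vel * speed_scale * perp[2]
  pos <- cbind(start[1] + c(0, cumsum(dx)),
               start[2] + c(0, cumsum(dy)))
  list(position = pos, sound_on = sound$on[seq_len(n)])
}

#' Export a target track as a per-step table
#'
#' @param schedule a [generate_trajectory()] schedule.
#' @param sound a [sound_duty_schedule()] schedule.
#' @param start length-2 starting position (m).
#' @param speed_scale m per schedule speed unit per step.
#' @return data.frame with columns `t`, `x`, `y`, `sound_on`.
#' @export
track_table <- function(schedule, sound, start = c(5, 3), speed_scale = 0.01) {
  tr <- target_track(start, schedule, sound, speed_scale)
  n <- schedule$n_steps
  data.frame(t = seq_len(n),
             x = tr$position[-1, 1],
             y = tr$position[-1, 2],
             sound_on = tr$sound_on)
}
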