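#' Configuration of one tracking trial
#'
#' @param snr_a_db auditory-pathway SNR in dB (applied to the raw sinusoids).
#' @param snr_v_db visual-cue SNR in dB (applied directly to the cue).
#' @param n_steps steps per trial.
#' @param mu learning rate.
#' @param w_init initial weight pair `c(w_a, w_v)`.
#' @param seed master seed for the trial; split into independent substreams
#'   for the trajectory, the sound duty cycle, the auditory noise and the
#'   visual noise.
#' @param learning logical, run the crossmodal weight updates.
#' @param noise_seed optional separate seed for the noise substreams; when
#'   `NULL` they derive from `seed`. Lets two runs share the same target
#'   trajectory and duty cycle while drawing independent noise, as in the
#'   paired model-vs-control evaluation.
#' @param sim a [cm_config()] with the remaining world/sensor parameters.
#' @return a list of class `trial_config`.
#' @export
trial_config <- function(snr_a_db = 3, snr_v_db = 3, n_steps = NULL,
                         mu = NULL, w_init = NULL, seed = 1L,
                         learning = TRUE, noise_seed = NULL,
                         sim = cm_config()) {
  if (is.null(n_steps)) n_steps <- sim$world$n_steps
  if (is.null(mu)) mu <- sim$learning$mu
  if (is.null(w_init)) w_init <- sim$learning$w_init
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("`n_steps` must be >= 1", call. = FALSE)
  structure(list(snr_a_db = snr_a_db, snr_v_db = snr_v_db,
                 n_steps = n_steps, mu = mu,
                 w_init = as.numeric(w_init), seed = as.integer(seed),
                 learning = isTRUE(learning),
                 noise_seed = if (is.null(noise_seed)) NULL else as.integer(noise_seed),
                 sim = sim),
            class = "trial_config")
}

#' Run one closed-loop tracking trial
#'
#' Executes the sense -> differentiate -> update-weights -> integrate -> act
#' loop for `config$n_steps` steps: the target follows its random zig-zag
#' track and duty-cycled sound emission; the binaural signal (with white
#' Gaussian noise at `snr_a_db` added to the raw sinusoids) passes through
#' the eardrum filter pair into the auditory cue; the visual cue is read
#' geometrically (noise at `snr_v_db` added directly to the cue); gated
#' crossmodal learning updates the weights; the fused output rotates the
#' agent on the spot toward the target. The agent initially points straight
#' ahead. Deterministic for a fixed `config$seed`.
#'
#' @param config a [trial_config()].
#' @param w optional [synaptic_weights()] carried in from a previous trial;
#'   defaults to `config$w_init` with learning rate `config$mu`.
#' @return an object of class `cm_trial`: list with `log` (per-step
#'   data.frame: `t`, agent pose, target position, cues, derivatives, gates,
#'   weights, fused output `v`, bearing error), `summary` (gated cue
#'   variances, normalized reliabilities, final weights), `weights`
#'   (final [synaptic_weights()]) and `config`.
#' @export
#' @examples
#' tr <- run_trial(trial_config(snr_a_db = 9, snr_v_db = 3, seed = 42))
#' tr$summary$w_final
run_trial <- function(config, w = NULL) {
  sim <- config$sim
  n <- config$n_steps
  if (is.null(w)) {
    w <- synaptic_weights(config$w_init[1], config$w_init[2], config$mu)
  } else {
    w <- synaptic_weights(w$w_a, w$w_v, config$mu)
  }
  seeds <- derive_seeds(config$seed, 5L)
  if (!is.null(config$noise_seed)) seeds[3:4] <- derive_seeds(config$noise_seed, 2L)

  schedule <- generate_trajectory(n, seed = seeds[1])
  duty <- sound_duty_schedule(n, seed = seeds[2])
  jit <- sim$world$spawn_jitter
  start <- unname(sim$world$target_start)
  if (!is.null(jit) && jit > 0)
    start[2] <- start[2] + with_seed(seeds[5], runif(1, -jit, jit))
  track <- target_track(start, schedule, duty, sim$world$speed_scale)

  params <- acoustic_params(sim$acoustics$f, sim$acoustics$d, sim$acoustics$c,
                            sim$acoustics$amplitude, sim$acoustics$sample_rate,
                            sim$acoustics$window)
  backend <- match.arg(sim$auditory$backend, c("filter", "surrogate"))
  if (backend == "filter") {
    spec <- eardrum_filter_spec(sim$auditory$passband, sim$auditory$order,
                                sim$acoustics$sample_rate,
                                sim$auditory$contra_gain,
                                sim$auditory$contra_delay)
    calib <- if (identical(sim$auditory$calib, "auto")) {
      calibrate_auditory(spec, params)
    } else as.numeric(sim$auditory$calib)
    nwin <- params$window
    phase <- 2 * pi * params$f * (seq_len(nwin) - 1L) / params$sample_rate
    n_on <- sum(track$sound_on)
    aud_noise <- with_seed(seeds[3],
                           if (n_on > 0) matrix(rnorm(2L * nwin * n_on), ncol = n_on)
                           else matrix(numeric(0), nrow = 2L * nwin, ncol = 0))
    snr_a_lin <- 10^(config$snr_a_db / 10)
  } else {
    aud_cue_noise <- with_seed(seeds[3], rnorm(n))
    sd_a <- cue_noise_sd(config$snr_a_db, sim$noise$ref_power)
  }
  vis_noise <- with_seed(seeds[4], rnorm(n))
  sd_v <- cue_noise_sd(config$snr_v_db, sim$noise$ref_power)

  half_v <- (sim$visual$width_deg / 2) * pi / 180
  depth_v <- sim$visual$depth_m
  dt <- sim$agent$dt
  # on-the-spot rotation: command_from_speed() + forward_kinematics()
  # collapse to theta <- theta - rot_gain * v * dt (position invariant)
  rot_gain <- 2 * sim$agent$motor_gain / sim$agent$l_m
  learn <- config$learning && w$mu > 0
  amp <- params$amplitude

  ax <- 0; ay <- 0; atheta <- pi / 2  # agent initially points straight ahead
  x_a <- numeric(n); x_v <- numeric(n)
  dx_a <- numeric(n); dx_v <- numeric(n)
  gate_a <- logical(n); gate_v <- logical(n)
  w_a <- numeric(n); w_v <- numeric(n)
  v_out <- numeric(n); bearing_err <- numeric(n)
  theta_log <- numeric(n)
  n_clamped <- 0L
  wa <- w$w_a; wv <- w$w_v; mu <- w$mu
  i_on <- 0L

  for (t in seq_len(n)) {
    tx <- track$position[t + 1L, 1L]; ty <- track$position[t + 1L, 2L]
    bearing <- wrap_angle(atheta - atan2(ty - ay, tx - ax))
    rng <- sqrt((tx - ax)^2 + (ty - ay)^2)
    ga <- track$sound_on[t]

    if (ga) {
      b_aud <- bearing
      if (abs(b_aud) > pi / 2) {
        b_aud <- sign(b_aud) * pi / 2
        n_clamped <- n_clamped + 1L
      }
      if (backend == "filter") {
        i_on <- i_on + 1L
        dphi <- 2 * pi * params$f * params$d * sin(b_aud) / params$c
        left <- amp * sin(phase - dphi / 2)
        right <- amp * sin(phase + dphi / 2)
        sdn <- sqrt(mean(left^2) / snr_a_lin)
        nz <- aud_noise[, i_on]
        left <- left + sdn * nz[seq_len(nwin)]
        right <- right + sdn * nz[nwin + seq_len(nwin)]
        p <- eardrum_powers(spec, left, right)
        xa_t <- clip(10 * log10(p[2] / p[1]) / calib)
      } else {
        xa_t <- clip(sin(b_aud) + sd_a * aud_cue_noise[t])
      }
    } else xa_t <- 0

    gv <- abs(bearing) <= half_v && rng <= depth_v
    xv_t <- if (gv) clip(bearing / half_v + sd_v * vis_noise[t]) else 0

    if (t == 1L) { dxa_t <- 0; dxv_t <- 0 } else {
      dxa_t <- (xa_t - x_a[t - 1L]) / dt
      dxv_t <- (xv_t - x_v[t - 1L]) / dt
    }

    if (learn) {
      if (ga) wa <- wa + mu * xa_t * dxv_t
      if (gv) wv <- wv + mu * xv_t * dxa_t
    }

    v <- wv * xv_t + wa * xa_t
    atheta <- wrap_angle(atheta - rot_gain * v * dt)

    x_a[t] <- xa_t; x_v[t] <- xv_t
    dx_a[t] <- dxa_t; dx_v[t] <- dxv_t
    gate_a[t] <- ga; gate_v[t] <- gv
    w_a[t] <- wa; w_v[t] <- wv
    v_out[t] <- v; bearing_err[t] <- bearing
    theta_log[t] <- atheta
  }

  if (max(abs(c(wa, wv))) > 1e3)
    warning("synaptic weights diverged beyond 1e3; trial completed anyway")
  if (n_clamped > 0L)
    attr(w, "n_clamped") <- n_clamped

  log <- data.frame(
    t = seq_len(n), agent_x = ax, agent_y = ay, agent_theta = theta_log,
    target_x = track$position[-1L, 1L], target_y = track$position[-1L, 2L],
    x_a = x_a, x_v = x_v, dx_a = dx_a, dx_v = dx_v,
    gate_a = gate_a, gate_v = gate_v,
    w_a = w_a, w_v = w_v, v = v_out, bearing_err = bearing_err
  )

  var_a <- if (sum(gate_a) >= 2L) cue_variance(x_a[gate_a]) else NA_real_
  var_v <- if (sum(gate_v) >= 2L) cue_variance(x_v[gate_v]) else NA_real_
  rel <- if (is.finite(var_a) && is.finite(var_v) && var_a > 0 && var_v > 0)
    normalized_reliabilities(var_a, var_v) else NULL

  w_out <- synaptic_weights(wa, wv, mu)
  structure(list(
    log = log,
    summary = list(var_a = var_a, var_v = var_v, reliabilities = rel,
                   w_final = c(w_a = wa, w_v = wv),
                   n_clamped = n_clamped,
                   snr_a_db = config$snr_a_db, snr_v_db = config$snr_v_db),
    weights = w_out,
    config = config
  ), class = "cm_trial")
}

#' Run a multi-trial learning session
#'
#' Runs `n_trials` tracking trials back to back under one SNR condition.
#' Synaptic weights are not reset between trials: each trial starts from the
#' weights learned in the previous one. Per-trial seeds are spawned from the
#' session seed.
#'
#' @param snr_a_db,snr_v_db the session's SNR condition in dB.
#' @param n_trials number of consecutive trials (20 in the standard
#'   protocols, 100 in the low-SNR protocol).
#' @param seed master session seed.
#' @param mu learning rate (0.09 standard, 0.01 for the low-SNR protocol).
#' @param w_init initial weight pair for trial 1.
#' @param n_steps steps per trial.
#' @param sim a [cm_config()].
#' @param keep_logs keep every per-step trial log (memory-heavy for large
#'   sessions); summaries are always kept.
#' @param learning logical; disable to freeze the weights.
#' @return an object of class `cm_session`: `trials` (per-trial summaries as
#'   a data.frame: end-of-trial weights, normalized weights, gated cue
#'   variances, normalized reliabilities), `logs` (list of `cm_trial`, if
#'   kept), `weights` (final [synaptic_weights()]), `condition`, `seed`.
#' @export
#' @examples
#' s <- run_session(snr_a_db = 3, snr_v_db = 21, n_trials = 3, seed = 1,
#'                  n_steps = 100)
#' coef(s)
run_session <- function(snr_a_db, snr_v_db, n_trials = 20L, seed = 1L,
                        mu = NULL, w_init = NULL, n_steps = NULL,
                        sim = cm_config(), keep_logs = FALSE,
                        learning = TRUE) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("session schedule must be nonempty", call. = FALSE)
  trial_seeds <- derive_seeds(seed, n_trials)
  if (is.null(mu)) mu <- sim$learning$mu
  if (is.null(w_init)) w_init <- sim$learning$w_init

  w <- synaptic_weights(w_init[1], w_init[2], mu)
  rows <- vector("list", n_trials)
  logs <- if (keep_logs) vector("list", n_trials) else NULL
  for (k in seq_len(n_trials)) {
    cfg <- trial_config(snr_a_db = snr_a_db, snr_v_db = snr_v_db,
                        n_steps = n_steps, mu = mu, w_init = w_init,
                        seed = trial_seeds[k], learning = learning, sim = sim)
    tr <- run_trial(cfg, w = w)
    w <- tr$weights
    s <- tr$summary
    nw <- tryCatch(normalize_weights(w), error = function(e) c(w_a = NA, w_v = NA))
    rows[[k]] <- data.frame(
      trial = k, w_a = s$w_final[["w_a"]], w_v = s$w_final[["w_v"]],
      w_a_norm = nw[["w_a"]], w_v_norm = nw[["w_v"]],
      var_a = s$var_a, var_v = s$var_v,
      rel_a_norm = if (is.null(s$reliabilities)) NA_real_ else s$reliabilities$rel_a_norm,
      rel_v_norm = if (is.null(s$reliabilities)) NA_real_ else s$reliabilities$rel_v_norm
    )
    if (keep_logs) logs[[k]] <- tr
  }
  structure(list(
    trials = do.call(rbind, rows),
    logs = logs,
    weights = w,
    condition = c(snr_a_db = snr_a_db, snr_v_db = snr_v_db),
    mu = mu, n_steps = if (is.null(n_steps)) sim$world$n_steps else n_steps,
    seed = seed
  ), class = "cm_session")
}

#' Run one of the standard session protocols over its SNR grid
#'
#' Protocols: `"fixed_audio"` keeps the auditory SNR at 3 dB and sweeps the
#' visual SNR over 6--21 dB in 3 dB steps; `"fixed_visual"` is the mirror
#' image; `"equal"` sweeps both SNRs together over 3--21 dB; `"low_snr"`
#' runs the two near-equal low-SNR conditions (3/6 and 6/3 dB) for 100
#' trials at learning rate 0.01.
#'
#' @param protocol protocol name.
#' @param n_trials trials per session (protocol default when `NULL`).
#' @param seed master seed; each grid condition gets a derived seed.
#' @param n_steps steps per trial.
#' @param sim a [cm_config()].
#' @return list of class `cm_protocol`: `sessions` (list of [run_session()]
#'   results) and `summary` (one row per condition: final normalized weights
#'   and session-median normalized reliabilities).
#' @export
run_protocol <- function(protocol = c("fixed_audio", "fixed_visual",
                                      "equal", "low_snr"),
                         n_trials = NULL, seed = 1L, n_steps = NULL,
                         sim = cm_config()) {
  protocol <- match.arg(protocol)
  grid <- switch(protocol,
    fixed_audio  = data.frame(snr_a = 3, snr_v = seq(6, 21, by = 3)),
    fixed_visual = data.frame(snr_a = seq(6, 21, by = 3), snr_v = 3),
    equal        = data.frame(snr_a = seq(3, 21, by = 3),
                              snr_v = seq(3, 21, by = 3)),
    low_snr      = data.frame(snr_a = c(3, 6), snr_v = c(6, 3))
  )
  mu <- if (protocol == "low_snr") 0.01 else sim$learning$mu
  if (is.null(n_trials)) n_trials <- if (protocol == "low_snr") 100L else 20L
  seeds <- derive_seeds(seed, nrow(grid))
  sessions <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- run_session(grid$snr_a[i], grid$snr_v[i], n_trials = n_trials,
                     seed = seeds[i], mu = mu, n_steps = n_steps, sim = sim)
    sessions[[i]] <- s
    last <- s$trials[nrow(s$trials), ]
    rows[[i]] <- data.frame(
      snr_a_db = grid$snr_a[i], snr_v_db = grid$snr_v[i],
      w_a = last$w_a, w_v = last$w_v,
      w_a_norm = last$w_a_norm, w_v_norm = last$w_v_norm,
      rel_a_norm = median(s$trials$rel_a_norm, na.rm = TRUE),
      rel_v_norm = median(s$trials$rel_v_norm, na.rm = TRUE)
    )
  }
  structure(list(protocol = protocol, sessions = sessions,
                 summary = do.call(rbind, rows), seed = seed),
            class = "cm_protocol")
}

# ---- methods ---------------------------------------------------------------

#' @export
print.cm_trial <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cm_trial> %d steps, SNR_a = %g dB, SNR_v = %g dB\n",
              nrow(x$log), s$snr_a_db, s$snr_v_db))
  cat(sprintf("  final weights: w_a = %.4f, w_v = %.4f\n",
              s$w_final[["w_a"]], s$w_final[["w_v"]]))
  cat(sprintf("  gated cue variances: var_a = %.4g, var_v = %.4g\n",
              s$var_a, s$var_v))
  if (!is.null(s$reliabilities))
    cat(sprintf("  normalized reliabilities: rel_a = %.3f, rel_v = %.3f\n",
                s$reliabilities$rel_a_norm, s$reliabilities$rel_v_norm))
  invisible(x)
}

#' @export
as.data.frame.cm_trial <- function(x, ...) x$log

#' @export
plot.cm_trial <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  plot(x$log$t, x$log$bearing_err * 180 / pi, type = "l",
       xlab = "time step", ylab = "bearing error (deg)", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::matplot(x$log$t, cbind(x$log$x_a, x$log$x_v), type = "l",
                    lty = 1, col = c("blue", "red"),
                    xlab = "time step", ylab = "directional cue")
  graphics::legend("topright", c("x_a", "x_v"), col = c("blue", "red"),
                   lty = 1, bty = "n")
  invisible(x)
}

#' @export
print.cm_session <- function(x, ...) {
  cat(sprintf("<cm_session> %d trials, SNR_a = %g dB, SNR_v = %g dB, mu = %g\n",
              nrow(x$trials), x$condition[["snr_a_db"]],
              x$condition[["snr_v_db"]], x$mu))
  cat(sprintf("  final weights: w_a = %.4f, w_v = %.4f (normalized %.3f / %.3f)\n",
              x$weights$w_a, x$weights$w_v,
              x$trials$w_a_norm[nrow(x$trials)],
              x$trials$w_v_norm[nrow(x$trials)]))
  invisible(x)
}

#' @export
coef.cm_session <- function(object, normalized = FALSE, ...) {
  if (normalized) normalize_weights(object$weights)
  else c(w_a = object$weights$w_a, w_v = object$weights$w_v)
}

#' @export
summary.cm_session <- function(object, ...) {
  last <- object$trials[nrow(object$trials), ]
  out <- list(
    condition = object$condition,
    n_trials = nrow(object$trials),
    w_final = c(w_a = last$w_a, w_v = last$w_v),
    w_norm = c(w_a = last$w_a_norm, w_v = last$w_v_norm),
    rel_norm = c(rel_a = median(object$trials$rel_a_norm, na.rm = TRUE),
                 rel_v = median(object$trials$rel_v_norm, na.rm = TRUE)),
    trials = object$trials
  )
  class(out) <- "summary.cm_session"
  out
}

#' @export
print.summary.cm_session <- function(x, ...) {
  cat(sprintf("Session: SNR_a = %g dB, SNR_v = %g dB, %d trials\n",
              x$condition[["snr_a_db"]], x$condition[["snr_v_db"]], x$n_trials))
  cat(sprintf("  final weights      : w_a = %.4f  w_v = %.4f\n",
              x$w_final[["w_a"]], x$w_final[["w_v"]]))
  cat(sprintf("  normalized weights : w_a = %.3f  w_v = %.3f\n",
              x$w_norm[["w_a"]], x$w_norm[["w_v"]]))
  cat(sprintf("  normalized reliab. : rel_a = %.3f  rel_v = %.3f (session median)\n",
              x$rel_norm[["rel_a"]], x$rel_norm[["rel_v"]]))
  invisible(x)
}

#' @export
plot.cm_session <- function(x, normalized = FALSE, ...) {
  tr <- x$trials
  if (normalized) {
    graphics::matplot(tr$trial, cbind(tr$w_a_norm, tr$w_v_norm), type = "b",
                      pch = c(1, 2), lty = 1, col = c("blue", "red"),
                      xlab = "trial", ylab = "normalized synaptic weight",
                      ylim = c(0, 1), ...)
  } else {
    graphics::matplot(tr$trial, cbind(tr$w_a, tr$w_v), type = "b",
                      pch = c(1, 2), lty = 1, col = c("blue", "red"),
                      xlab = "trial", ylab = "synaptic weight", ...)
  }
  graphics::legend("topleft", c("w_a", "w_v"), col = c("blue", "red"),
                   pch = c(1, 2), bty = "n")
  invisible(x)
}
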