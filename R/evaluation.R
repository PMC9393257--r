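#' MLE control weights from normalized reliabilities
#'
#' The maximum-likelihood-estimation control sets each synaptic weight to the
#' corresponding normalized cue reliability and disables learning.
#'
#' @param rel a [normalized_reliabilities()] pair.
#' @return a [synaptic_weights()] with `mu = 0`.
#' @export
#' @examples
#' mle_weights(normalized_reliabilities(1, 3))
mle_weights <- function(rel) {
  if (!inherits(rel, "reliability_pair"))
    stop("`rel` must be a reliability_pair", call. = FALSE)
  synaptic_weights(w_a = rel$rel_a_norm, w_v = rel$rel_v_norm, mu = 0)
}

#' Per-trial location estimate from a trial log
#'
#' Operationalizes the "average relative target location" of one trial:
#' for the fused modes, the time average over gated steps (sound on or
#' target visible) of the weighted location signal `w_v * x_v + w_a * x_a`;
#' for the unisensory modes, the time average of the corresponding cue over
#' its own gate. With `statistic = "accuracy"` the same gated signal is
#' summarized as `1 - mean(|signal|)`, an accuracy score in which higher
#' values mean lower localization error.
#'
#' @param trial a [run_trial()] result.
#' @param mode one of `"fused"`, `"auditory"`, `"visual"`.
#' @param weights weight pair for the fused mode (a [synaptic_weights()] or
#'   numeric `c(w_a, w_v)`); defaults to the trial's final weights.
#' @param statistic `"location"` (signed time average) or `"accuracy"`.
#' @return numeric scalar estimate.
#' @export
trial_location_estimate <- function(trial,
                                    mode = c("fused", "auditory", "visual"),
                                    weights = NULL,
                                    statistic = c("location", "accuracy")) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  log <- trial$log
  if (mode == "fused") {
    if (is.null(weights)) weights <- trial$weights
    if (inherits(weights, "synaptic_weights"))
      weights <- c(weights$w_a, weights$w_v)
    gate <- log$gate_a | log$gate_v
    sig <- weights[2] * log$x_v + weights[1] * log$x_a
  } else if (mode == "auditory") {
    gate <- log$gate_a
    sig <- log$x_a
  } else {
    gate <- log$gate_v
    sig <- log$x_v
  }
  if (!any(gate))
    stop(sprintf("no gated steps for mode '%s'", mode), call. = FALSE)
  if (statistic == "location") mean(sig[gate]) else 1 - mean(abs(sig[gate]))
}

#' Robust linear fit with Tukey bisquare weights
#'
#' First-order polynomial `f(x) = p1 * x + p2` fit by iteratively reweighted
#' least squares. Residuals are scaled by `1.4826 * MAD`; observations with
#' scaled residuals beyond the tuning constant (4.685) receive exactly zero
#' weight, so gross outliers are discarded rather than merely down-weighted.
#' Iteration stops when the relative coefficient change falls below `tol` or
#' after `max_iter` iterations. `r2`, `sse` and `rmse` are computed on the
#' weighted fit.
#'
#' @param x,y numeric vectors (>= 3 points).
#' @param tuning bisquare tuning constant.
#' @param tol relative coefficient-change convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return a list of class `cm_robust_fit` with `p1` (slope), `p2`
#'   (intercept), `r2`, `sse`, `rmse`, `weights` (final observation
#'   weights), `iterations`, `converged`.
#' @export
#' @examples
#' robust_linear_fit(1:10, 2 * (1:10) + 1)$p1
robust_linear_fit <- function(x, y, tuning = 4.685, tol = 1e-8,
                              max_iter = 50L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` is degenerate (zero variance)", call. = FALSE)

  X <- cbind(x, 1)
  beta <- stats::lm.fit(X, y)$coefficients
  wts <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    r <- y - X %*% beta
    s <- 1.4826 * stats::median(abs(r))  # MAD about zero, as in M-estimation
    if (s <= .Machine$double.eps^0.5) { converged <- TRUE; break }
    u <- as.numeric(r) / (tuning * s)
    new_wts <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(new_wts > 0) < 2L) {
      # residual scale collapsed onto a cluster; keep the last stable fit
      converged <- TRUE
      break
    }
    wts <- new_wts
    beta_new <- stats::lm.wfit(X, y, wts)$coefficients
    if (max(abs(beta_new - beta)) <= tol * max(abs(beta), tol)) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  fitted <- as.numeric(X %*% beta)
  r <- y - fitted
  sse <- sum(wts * r^2)
  ybar <- sum(wts * y) / sum(wts)
  sst <- sum(wts * (y - ybar)^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  structure(list(p1 = unname(beta[1]), p2 = unname(beta[2]),
                 r2 = r2, sse = sse,
                 rmse = sqrt(sse / max(n - 2, 1)),
                 weights = wts, iterations = iter, converged = converged),
            class = "cm_robust_fit")
}

#' @export
print.cm_robust_fit <- function(x, ...) {
  cat(sprintf("<robust bisquare fit> f(x) = %.4f x + %.4f\n", x$p1, x$p2))
  cat(sprintf("  r2 = %.4f, sse = %.4g, rmse = %.4g (%d iterations%s)\n",
              x$r2, x$sse, x$rmse, x$iterations,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Two-sample one-tailed Welch t-test
#'
#' Unequal-variance t statistic with Welch--Satterthwaite degrees of freedom
#' and a right-tailed p-value (alternative: mean of `x` greater than mean of
#' `y`).
#'
#' @param x,y numeric samples (length >= 2 each).
#' @return a list of class `cm_t_test` with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need at least 2 observations", call. = FALSE)
  ht <- stats::t.test(x, y, alternative = "greater", var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value),
            class = "cm_t_test")
}

#' @export
print.cm_t_test <- function(x, ...) {
  cat(sprintf("Welch one-tailed t-test: t = %.4f, df = %.4f, p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Learn session-end weights for every evaluation SNR condition
#'
#' Runs one 20-trial learning session per SNR condition used by the
#' randomized evaluation (equal SNRs from \{3, 9, 12, 15, 18, 21\} dB and
#' one-modality-varied conditions with the other modality at 3 dB) and
#' returns the session-end normalized weights.
#'
#' @param seed master seed; each condition gets a derived session seed.
#' @param n_trials trials per learning session.
#' @param n_steps steps per trial.
#' @param sim a [cm_config()].
#' @param snr_set the SNR levels (dB) drawn by the evaluation.
#' @return data.frame with columns `snr_a_db`, `snr_v_db`, `w_a`, `w_v`
#'   (raw), `w_a_norm`, `w_v_norm` (normalized, the model weights used in
#'   evaluation) and `rel_a_norm`, `rel_v_norm` (session-median normalized
#'   reliabilities, the MLE control weights).
#' @export
learn_condition_weights <- function(seed = 1L, n_trials = 20L, n_steps = NULL,
                                    sim = cm_config(),
                                    snr_set = c(3, 9, 12, 15, 18, 21)) {
  grid <- unique(rbind(
    data.frame(snr_a = snr_set, snr_v = snr_set),            # equal SNRs
    data.frame(snr_a = setdiff(snr_set, 3), snr_v = 3),      # audio varied
    data.frame(snr_a = 3, snr_v = setdiff(snr_set, 3))       # visual varied
  ))
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- run_session(grid$snr_a[i], grid$snr_v[i], n_trials = n_trials,
                     seed = seeds[i], n_steps = n_steps, sim = sim)
    nw <- normalize_weights(s$weights)
    rows[[i]] <- data.frame(snr_a_db = grid$snr_a[i], snr_v_db = grid$snr_v[i],
                            w_a = s$weights$w_a, w_v = s$weights$w_v,
                            w_a_norm = nw[["w_a"]], w_v_norm = nw[["w_v"]],
                            rel_a_norm = median(s$trials$rel_a_norm, na.rm = TRUE),
                            rel_v_norm = median(s$trials$rel_v_norm, na.rm = TRUE))
  }
  do.call(rbind, rows)
}

#' Compare the learned model against the MLE control
#'
#' Runs `n_trials` randomized fixed-weight evaluation trials. Before each
#' trial the SNR condition is drawn: with probability 1/2 both modalities
#' get one SNR from `snr_set`; otherwise one randomly chosen modality draws
#' from `snr_set` while the other is fixed at 3 dB. Each trial comprises two
#' tracking runs with learning disabled, each on its own randomly generated
#' target path, duty cycle and noise: one with the session-end normalized
#' learned weights for that condition (model) and one with weights set to
#' the condition's normalized cue reliabilities from the same learning
#' sessions (MLE control). Per-trial estimates of both fused models and of
#' the two unisensory cues feed a robust bisquare regression (model vs MLE),
#' one-tailed Welch t-tests of fused against unisensory estimates, and a
#' per-condition-group table of estimate variances.
#'
#' Two operationalizations of the per-trial "average relative target
#' location" are computed (see [trial_location_estimate()]): the signed
#' gated time average (`"location"`) and the accuracy score
#' `1 - mean(|location signal|)` (`"accuracy"`), in which a higher estimate
#' means a lower localization error. `statistic` selects which one feeds the
#' regression and the t-tests; both are kept in `estimates`. The accuracy
#' score is the default: in a closed loop the signed time average of the
#' very signal that drives the orientation response telescopes to a
#' geometry-determined quantity and so carries almost no information about
#' cue quality (see the package vignette).
#'
#' @param learned weights per condition from [learn_condition_weights()];
#'   computed internally (20-trial sessions, seed derived from `seed`) when
#'   `NULL`.
#' @param n_trials number of evaluation trials.
#' @param seed master seed.
#' @param n_steps steps per trial.
#' @param sim a [cm_config()].
#' @param snr_set SNR levels (dB) drawn for the conditions.
#' @param statistic which per-trial estimate feeds the regression and
#'   t-tests: `"accuracy"` (default) or `"location"`.
#' @return an object of class `cm_mle_comparison`: `estimates` (one row per
#'   trial: condition, model/MLE/auditory/visual location estimates and
#'   accuracy scores), `fit` (the [robust_linear_fit()] of model on MLE),
#'   `t_tests` (the four Welch tests on accuracy scores), `variances`
#'   (per-condition-group estimate variances from [variance_comparison()]),
#'   `learned` (the weight table used).
#' @export
#' @examples
#' \donttest{
#' cmp <- mle_comparison(n_trials = 10, seed = 1, n_steps = 100)
#' cmp$fit$r2
#' }
mle_comparison <- function(learned = NULL, n_trials = 50L, seed = 1L,
                           n_steps = NULL, sim = cm_config(),
                           snr_set = c(3, 9, 12, 15, 18, 21),
                           statistic = c("accuracy", "location")) {
  statistic <- match.arg(statistic)
  seeds <- derive_seeds(seed, 2L)
  if (is.null(learned))
    learned <- learn_condition_weights(seed = seeds[1], n_steps = n_steps,
                                       sim = sim, snr_set = snr_set)
  eval_seeds <- derive_seeds(seeds[2], 2L * n_trials + 1L)
  cond <- with_seed(eval_seeds[2L * n_trials + 1L], {
    equal <- runif(n_trials) < 0.5
    lvl <- snr_set[sample.int(length(snr_set), n_trials, replace = TRUE)]
    aud_varied <- runif(n_trials) < 0.5
    data.frame(
      snr_a = ifelse(equal, lvl, ifelse(aud_varied, lvl, 3)),
      snr_v = ifelse(equal, lvl, ifelse(aud_varied, 3, lvl))
    )
  })

  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    sa <- cond$snr_a[i]; sv <- cond$snr_v[i]
    lw <- learned[learned$snr_a_db == sa & learned$snr_v_db == sv, ]
    if (nrow(lw) != 1L)
      stop(sprintf("no learned weights for condition SNR_a=%g, SNR_v=%g", sa, sv),
           call. = FALSE)
    cfg <- trial_config(snr_a_db = sa, snr_v_db = sv, n_steps = n_steps,
                        mu = 0, seed = eval_seeds[i], learning = FALSE,
                        sim = sim)
    model_w <- synaptic_weights(lw$w_a_norm, lw$w_v_norm, mu = 0)
    tr_model <- run_trial(cfg, w = model_w)

    mle_w <- mle_weights(normalized_reliabilities(
      1 / lw$rel_a_norm, 1 / lw$rel_v_norm))
    cfg_mle <- trial_config(snr_a_db = sa, snr_v_db = sv, n_steps = n_steps,
                            mu = 0, seed = eval_seeds[n_trials + i],
                            learning = FALSE, sim = sim)
    tr_mle <- run_trial(cfg_mle, w = mle_w)

    est_na <- function(...) tryCatch(trial_location_estimate(...),
                                     error = function(e) NA_real_)
    rows[[i]] <- data.frame(
      trial = i, snr_a_db = sa, snr_v_db = sv,
      group = if (sa == sv) "equal" else if (sa > sv) "snr_a_gt_v" else "snr_v_gt_a",
      model = est_na(tr_model, "fused", model_w),
      mle = est_na(tr_mle, "fused", mle_w),
      auditory = est_na(tr_model, "auditory"),
      visual = est_na(tr_model, "visual"),
      model_acc = est_na(tr_model, "fused", model_w, "accuracy"),
      mle_acc = est_na(tr_mle, "fused", mle_w, "accuracy"),
      auditory_acc = est_na(tr_model, "auditory", statistic = "accuracy"),
      auditory_acc_mle = est_na(tr_mle, "auditory", statistic = "accuracy"),
      visual_acc = est_na(tr_model, "visual", statistic = "accuracy"),
      visual_acc_mle = est_na(tr_mle, "visual", statistic = "accuracy")
    )
  }
  est <- do.call(rbind, rows)

  if (statistic == "accuracy") {
    x_mle <- est$mle_acc; y_model <- est$model_acc
    s_model <- est$model_acc; s_mle <- est$mle_acc
    s_aud <- est$auditory_acc; s_aud_mle <- est$auditory_acc_mle
    s_vis <- est$visual_acc; s_vis_mle <- est$visual_acc_mle
  } else {
    x_mle <- est$mle; y_model <- est$model
    s_model <- est$model; s_mle <- est$mle
    s_aud <- est$auditory; s_aud_mle <- est$auditory
    s_vis <- est$visual; s_vis_mle <- est$visual
  }
  ok <- is.finite(x_mle) & is.finite(y_model)
  fit <- robust_linear_fit(x_mle[ok], y_model[ok])
  tt_na <- function(x, y) {
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) < 2L)
      return(structure(list(t = NA_real_, df = NA_real_, p = NA_real_),
                       class = "cm_t_test"))
    welch_t_test(x[keep], y[keep])
  }
  t_tests <- list(
    model_vs_auditory = tt_na(s_model, s_aud),
    model_vs_visual = tt_na(s_model, s_vis),
    mle_vs_auditory = tt_na(s_mle, s_aud_mle),
    mle_vs_visual = tt_na(s_mle, s_vis_mle)
  )
  structure(list(estimates = est, fit = fit, t_tests = t_tests,
                 variances = variance_comparison(est),
                 statistic = statistic,
                 learned = learned, seed = seed),
            class = "cm_mle_comparison")
}

#' Per-condition variances of the four location estimates
#'
#' Across-trial variance of the fused-learned, fused-MLE, auditory-only and
#' visual-only per-trial location estimates, per condition group.
#'
#' @param estimates the `estimates` data.frame of a [mle_comparison()] (or
#'   any data.frame with columns `group`, `model`, `mle`, `auditory`,
#'   `visual`).
#' @return data.frame with one row per group (>= 2 trials required) plus a
#'   pooled `"all"` row.
#' @export
variance_comparison <- function(estimates) {
  need <- c("group", "model", "mle", "auditory", "visual")
  if (!all(need %in% names(estimates)))
    stop("`estimates` must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  groups <- c(split(estimates, estimates$group), list(all = estimates))
  groups <- Filter(function(g) nrow(g) >= 2L, groups)
  if (!length(groups))
    stop("need at least 2 trials in some condition group", call. = FALSE)
  do.call(rbind, lapply(names(groups), function(g) {
    e <- groups[[g]]
    data.frame(group = g, n = nrow(e),
               var_model = stats::var(e$model, na.rm = TRUE),
               var_mle = stats::var(e$mle, na.rm = TRUE),
               var_auditory = stats::var(e$auditory, na.rm = TRUE),
               var_visual = stats::var(e$visual, na.rm = TRUE))
  }))
}

#' @export
print.cm_mle_comparison <- function(x, ...) {
  cat(sprintf("<cm_mle_comparison> %d evaluation trials\n", nrow(x$estimates)))
  print(x$fit)
  invisible(x)
}

#' @export
summary.cm_mle_comparison <- function(object, ...) {
  structure(list(fit = object$fit, t_tests = object$t_tests,
                 variances = object$variances,
                 n = nrow(object$estimates)),
            class = "summary.cm_mle_comparison")
}

#' @export
print.summary.cm_mle_comparison <- function(x, ...) {
  cat(sprintf("MLE comparison over %d randomized evaluation trials\n", x$n))
  print(x$fit)
  cat("\nWelch one-tailed t-tests (fused accuracy > unisensory accuracy):\n")
  for (nm in names(x$t_tests)) {
    tt <- x$t_tests[[nm]]
    cat(sprintf("  %-18s t = %8.3f  df = %7.2f  p = %.3g\n",
                nm, tt$t, tt$df, tt$p))
  }
  cat("\nEstimate variances by condition group:\n")
  print(x$variances, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cm_mle_comparison <- function(x, ...) {
  e <- x$estimates
  cols <- c(equal = "darkgreen", snr_a_gt_v = "blue", snr_v_gt_a = "red")
  if (identical(x$statistic, "location")) {
    xv <- e$mle; yv <- e$model
  } else {
    xv <- e$mle_acc; yv <- e$model_acc
  }
  plot(xv, yv, col = cols[e$group], pch = 16,
       xlab = "MLE model estimate", ylab = "learned model estimate", ...)
  graphics::abline(x$fit$p2, x$fit$p1)
  graphics::legend("topleft", names(cols), col = cols, pch = 16, bty = "n")
  invisible(x)
}
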