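#' Write a trial log as CSV
#'
#' @param trial a [run_trial()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  utils::write.csv(trial$log, path, row.names = FALSE)
  invisible(path)
}

#' Write a session to a directory (per-trial CSV logs + JSON summary)
#'
#' The JSON summary carries the condition, seed, per-trial end-of-trial
#' weights, variances and reliabilities; per-step logs (one CSV per trial)
#' are written only when the session was run with `keep_logs = TRUE`.
#'
#' @param session a [run_session()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    condition = as.list(session$condition),
    mu = session$mu,
    n_steps = session$n_steps,
    seed = session$seed,
    final_weights = list(w_a = session$weights$w_a, w_v = session$weights$w_v),
    trials = session$trials
  )
  jsonlite::write_json(summary, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  if (!is.null(session$logs)) {
    for (k in seq_along(session$logs)) {
      write_trial_csv(session$logs[[k]],
                      file.path(dir, sprintf("trial_%03d.csv", k)))
    }
  }
  invisible(dir)
}

#' Write an MLE comparison to a directory
#'
#' Emits `regression.json` (slope, intercept, r2, sse, rmse), a scatter CSV
#' of per-trial model vs MLE estimates, a t-test CSV, and a variance CSV.
#'
#' @param cmp a [mle_comparison()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mle_comparison <- function(cmp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(p1 = cmp$fit$p1, p2 = cmp$fit$p2, r2 = cmp$fit$r2,
         sse = cmp$fit$sse, rmse = cmp$fit$rmse, n = nrow(cmp$estimates)),
    file.path(dir, "regression.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(cmp$estimates, file.path(dir, "estimates.csv"),
                   row.names = FALSE)
  tt <- do.call(rbind, lapply(names(cmp$t_tests), function(nm) {
    x <- cmp$t_tests[[nm]]
    data.frame(comparison = nm, t = x$t, df = x$df, p = x$p)
  }))
  utils::write.csv(tt, file.path(dir, "t_tests.csv"), row.names = FALSE)
  utils::write.csv(cmp$variances, file.path(dir, "variances.csv"),
                   row.names = FALSE)
  invisible(dir)
}
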