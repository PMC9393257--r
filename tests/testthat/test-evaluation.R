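test_that("MLE weights equal the normalized reliabilities with learning off", {
  expect_equal(mle_weights(normalized_reliabilities(2, 2))$w_a, 0.5)
  w <- mle_weights(normalized_reliabilities(1, 3))
  expect_equal(c(w$w_a, w$w_v), c(0.75, 0.25))
  expect_equal(w$w_a + w$w_v, 1)
  expect_equal(w$mu, 0)
  expect_error(mle_weights(list(rel_a_norm = 0.5)), "reliability_pair")
})

test_that("per-trial location estimates average the gated signals", {
  fake <- list(log = data.frame(
    t = 1:4,
    x_a = c(0.5, 0.5, 0, 0.5), x_v = c(0.5, 0.5, 0.5, 0),
    gate_a = c(TRUE, TRUE, FALSE, TRUE), gate_v = c(TRUE, TRUE, TRUE, FALSE)
  ), weights = synaptic_weights(0.5, 0.5, 0))
  class(fake) <- "cm_trial"
  w <- c(0.5, 0.5)
  expect_equal(trial_location_estimate(fake, "fused", w),
               mean(c(0.5, 0.5, 0.25, 0.25)))
  expect_equal(trial_location_estimate(fake, "auditory"), 0.5)
  expect_equal(trial_location_estimate(fake, "visual"), 0.5)
  expect_equal(trial_location_estimate(fake, "auditory", statistic = "accuracy"),
               0.5)

  none <- fake
  none$log$gate_v <- FALSE
  expect_error(trial_location_estimate(none, "visual"), "no gated steps")
})

test_that("robust bisquare fit recovers lines and rejects gross outliers", {
  x <- 1:20
  y <- 2 * x + 1
  f <- robust_linear_fit(x, y)
  expect_equal(f$p1, 2, tolerance = 1e-10)
  expect_equal(f$p2, 1, tolerance = 1e-8)
  expect_equal(f$r2, 1)
  expect_equal(f$sse, 0, tolerance = 1e-12)

  # oracle: ordinary least squares on the clean points
  set.seed(3)
  yn <- 2 * x + 1 + rnorm(20, sd = 0.05)
  x_o <- c(x, 10.5); y_o <- c(yn, 60)   # one gross outlier
  f_o <- robust_linear_fit(x_o, y_o)
  ols_clean <- coef(lm(yn ~ x))
  expect_lt(abs(f_o$p1 - ols_clean[2]) / abs(ols_clean[2]), 0.01)
  expect_equal(f_o$weights[21], 0)

  expect_error(robust_linear_fit(rep(1, 5), 1:5), "degenerate")
  expect_error(robust_linear_fit(1:2, 1:2), "3 points")
})

test_that("robust fit agrees with an independent M-estimator on noisy data", {
  skip_if_not_installed("MASS")
  set.seed(9)
  x <- runif(60, 0, 10)
  y <- 1.4 * x - 2 + rnorm(60, sd = 0.8)
  y[c(5, 40)] <- y[c(5, 40)] + 15
  ours <- robust_linear_fit(x, y)
  ref <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685, maxit = 100)
  expect_equal(ours$p1, unname(coef(ref)[2]), tolerance = 0.02)
  expect_equal(ours$p2, unname(coef(ref)[1]), tolerance = 0.15)
})

test_that("Welch t-test matches the closed-form statistic and a permutation oracle", {
  x <- c(1.1, 2.3, 3.2, 4.8, 2.2)
  y <- c(0.3, 0.9, 1.4, 0.8)
  res <- welch_t_test(x, y)
  # hand evaluation of the Welch formula
  t_hand <- (mean(x) - mean(y)) / sqrt(var(x) / 5 + var(y) / 4)
  df_hand <- (var(x) / 5 + var(y) / 4)^2 /
    ((var(x) / 5)^2 / 4 + (var(y) / 4)^2 / 3)
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$df, df_hand, tolerance = 1e-9)
  expect_equal(res$p, pt(t_hand, df_hand, lower.tail = FALSE), tolerance = 1e-12)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")

  # permutation oracle on a small sample
  set.seed(4)
  xs <- rnorm(6, mean = 1); ys <- rnorm(5)
  obs <- welch_t_test(xs, ys)
  pooled <- c(xs, ys)
  perm <- replicate(4000, {
    idx <- sample(11, 6)
    a <- pooled[idx]; b <- pooled[-idx]
    (mean(a) - mean(b)) / sqrt(var(a) / 6 + var(b) / 5)
  })
  p_perm <- mean(perm >= obs$t)
  expect_lt(abs(obs$p - p_perm), 0.05)
})

test_that("variance comparison reports per-group estimate variances", {
  est <- data.frame(
    group = rep(c("equal", "snr_a_gt_v"), each = 4),
    model = c(rep(0.5, 4), 1:4), mle = c(rep(0.5, 4), 2:5),
    auditory = rnorm(8), visual = rnorm(8)
  )
  v <- variance_comparison(est)
  expect_equal(v$var_model[v$group == "equal"], 0)
  expect_equal(v$var_mle[v$group == "snr_a_gt_v"], var(2:5))
  expect_true("all" %in% v$group)
  expect_error(variance_comparison(est[0, ]), "at least 2")
  expect_error(variance_comparison(data.frame(a = 1)), "must contain")
})

test_that("fused MLE estimates beat unisensory variance per the closed form", {
  # oracle: for independent Gaussian cues the reliability-weighted average has
  # variance var_a * var_v / (var_a + var_v)
  set.seed(11)
  var_a <- 0.36; var_v <- 0.09
  n_steps <- 40; n_trials <- 400
  rel <- normalized_reliabilities(var_a, var_v)
  w <- mle_weights(rel)
  est <- t(replicate(n_trials, {
    xa <- rnorm(n_steps, 0, sqrt(var_a))
    xv <- rnorm(n_steps, 0, sqrt(var_v))
    c(fused = mean(w$w_a * xa + w$w_v * xv), aud = mean(xa), vis = mean(xv))
  }))
  closed <- var_a * var_v / (var_a + var_v) / n_steps
  expect_equal(var(est[, "fused"]), closed, tolerance = 0.2)
  expect_lt(var(est[, "fused"]), min(var(est[, "aud"]), var(est[, "vis"])))
})
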