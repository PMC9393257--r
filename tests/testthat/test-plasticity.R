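test_that("the multisensory neuron computes the weighted cue sum", {
  w <- synaptic_weights(w_a = 0.3, w_v = 0.5)
  expect_equal(fuse_cues(w, cue_frame(x_a = -0.4, x_v = 0.2)), -0.02)
  expect_equal(fuse_cues(w, cue_frame(x_a = 0, x_v = 0)), 0)
  w0 <- synaptic_weights(w_a = 0, w_v = 0.5)
  expect_equal(fuse_cues(w0, cue_frame(x_a = 0.9, x_v = 0.2)), 0.1)
})

test_that("cue derivative is a backward difference with a zero first frame", {
  expect_equal(cue_derivative(0.4, 0.4), 0)
  expect_equal(cue_derivative(0, 1, dt = 1), 1)
  expect_equal(cue_derivative(NULL, 0.7), 0)
  # an onset from exact zero has nonzero dynamics
  expect_equal(cue_derivative(0, 0.4), 0.4)
  expect_equal(cue_derivative(0.4, 0), -0.4)
})

test_that("weight updates follow the gated crossmodal rule", {
  w <- synaptic_weights(0.1, 0.1, mu = 0.09)
  up <- update_weights(w, cue_frame(x_a = 0.5, x_v = 0, dx_a = 0, dx_v = 0.2,
                                    gate_a = TRUE, gate_v = TRUE))
  expect_equal(up$w_a - w$w_a, 0.009)   # mu * x_a * dx_v
  expect_equal(up$w_v, w$w_v)           # dx_a = 0

  # a zero companion derivative freezes the weight regardless of the cue
  frozen <- update_weights(w, cue_frame(x_a = 0.9, x_v = 0.9, dx_a = 0,
                                        dx_v = 0, gate_a = TRUE, gate_v = TRUE))
  expect_equal(c(frozen$w_a, frozen$w_v), c(w$w_a, w$w_v))

  # gates block updates exactly
  gated <- update_weights(w, cue_frame(x_a = 0.5, x_v = 0.5, dx_a = 1, dx_v = 1,
                                       gate_a = FALSE, gate_v = TRUE))
  expect_equal(gated$w_a, w$w_a)
  expect_false(gated$w_v == w$w_v)
})

test_that("updates are crossmodal only and linear in each factor", {
  base <- cue_frame(x_a = 0.4, x_v = 0.6, dx_a = 0.3, dx_v = 0.2)
  w <- synaptic_weights(0, 0, mu = 0.09)
  d_wa <- update_weights(w, base)$w_a
  # changing the same-modality derivative or other-modality cue leaves dw_a alone
  probe1 <- cue_frame(x_a = 0.4, x_v = -0.9, dx_a = 5, dx_v = 0.2)
  expect_equal(update_weights(w, probe1)$w_a, d_wa)
  # scaling mu, x_a or dx_v scales dw_a linearly
  w2 <- synaptic_weights(0, 0, mu = 0.18)
  expect_equal(update_weights(w2, base)$w_a, 2 * d_wa)
  double_xa <- cue_frame(x_a = 0.8, x_v = 0.6, dx_a = 0.3, dx_v = 0.2)
  expect_equal(update_weights(w, double_xa)$w_a, 2 * d_wa)
  double_dxv <- cue_frame(x_a = 0.4, x_v = 0.6, dx_a = 0.3, dx_v = 0.4)
  expect_equal(update_weights(w, double_dxv)$w_a, 2 * d_wa)
})

test_that("weights stabilize under constant or zero cues", {
  w <- synaptic_weights(0.2, 0.3, mu = 0.09)
  prev_a <- 0.5; prev_v <- -0.2
  for (t in 1:20) {
    f <- cue_frame(x_a = 0.5, x_v = -0.2,
                   dx_a = cue_derivative(prev_a, 0.5),
                   dx_v = cue_derivative(prev_v, -0.2))
    w <- update_weights(w, f)
  }
  expect_equal(c(w$w_a, w$w_v), c(0.2, 0.3))
})

test_that("normalize_weights projects onto the simplex and is scale-invariant", {
  expect_equal(normalize_weights(synaptic_weights(0.2, 0.6)),
               c(w_a = 0.25, w_v = 0.75))
  expect_equal(normalize_weights(c(0.4, 0.4)), c(w_a = 0.5, w_v = 0.5))
  expect_equal(normalize_weights(c(1, 3)), normalize_weights(c(5, 15)))
  expect_error(normalize_weights(c(0.5, -0.5)), "zero")
})
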