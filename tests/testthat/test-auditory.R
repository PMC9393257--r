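test_that("compiled IIR kernel agrees with signal::filter", {
  bf <- signal::butter(2, c(1000, 4000) / 22050, type = "pass")
  set.seed(1)
  x <- rnorm(256)
  expect_equal(crossmodal:::.iir_filter_cpp(as.numeric(bf$b), as.numeric(bf$a), x),
               as.numeric(signal::filter(bf, x)), tolerance = 1e-10)
})

test_that("eardrum filter pair is linear, mirrored and band-limited", {
  silent <- list(left = numeric(256), right = numeric(256))
  out <- eardrum_filter(silent, test_spec)
  expect_true(all(out$left == 0) && all(out$right == 0))

  w0 <- crossmodal:::binaural_window(0, acoustic_params(window = 256))
  out0 <- eardrum_filter(w0, test_spec)
  expect_equal(mean(out0$left^2), mean(out0$right^2), tolerance = 1e-12)

  expect_error(eardrum_filter(list(left = numeric(8), right = numeric(8)),
                              test_spec), "transient")

  resp <- eardrum_response(test_spec)
  peak <- max(resp$gain_db)
  expect_lt(resp$gain_db[resp$freq_hz == 500], peak - 10)
  expect_lt(resp$gain_db[resp$freq_hz == 8000], peak - 10)
})

test_that("binaural power difference peaks near the 2.2 kHz carrier", {
  freqs <- seq(600, 6000, by = 100)
  dp <- vapply(freqs, function(f) {
    params <- acoustic_params(f = f, window = 512L)
    w <- crossmodal:::binaural_window(45 * pi / 180, params)
    p <- crossmodal:::eardrum_powers(test_spec, w$left, w$right)
    10 * log10(p[2] / p[1])
  }, numeric(1))
  f_peak <- freqs[which.max(dp)]
  expect_gt(f_peak, 1700)
  expect_lt(f_peak, 2900)
})

test_that("calibrated auditory cue is odd, monotone and saturates at +/-1", {
  calib <- calibrate_auditory(test_spec, test_params)
  expect_gt(calib, 0)
  expect_identical(calib, calibrate_auditory(test_spec, test_params))  # memoized

  sweep <- auditory_sweep(test_spec, test_params, n_theta = 181L)
  cue <- crossmodal:::clip(sweep$dp_db / calib)
  expect_equal(cue, -rev(cue), tolerance = 1e-10)          # odd
  expect_true(all(diff(sweep$dp_db) > 0))                  # monotone
  expect_equal(cue[1], -1)                                 # saturation at -90 deg
  expect_equal(cue[181], 1)
  expect_equal(cue[91], 0, tolerance = 1e-12)              # centred target
  expect_true(all(abs(cue) <= 1))
})

test_that("auditory cue is zero and inaudible for silent input", {
  silent <- eardrum_filter(list(left = numeric(128), right = numeric(128)),
                           test_spec)
  cue <- auditory_cue(silent, calib = 10)
  expect_identical(cue$x_a, 0)
  expect_false(cue$audible)
})

test_that("lower input SNR strictly inflates cue variance (noise pass-through)", {
  calib <- calibrate_auditory(test_spec, test_params)
  cue_at <- function(snr, n = 120) {
    vapply(seq_len(n), function(i) {
      w <- crossmodal:::binaural_window(0.3, test_params)
      filt <- eardrum_filter(list(left = add_awgn(w$left, snr),
                                  right = add_awgn(w$right, snr)), test_spec)
      auditory_cue(filt, calib)$x_a
    }, numeric(1))
  }
  set.seed(42)
  v3 <- var(cue_at(3)); v9 <- var(cue_at(9)); v21 <- var(cue_at(21))
  expect_gt(v3, v9)
  expect_gt(v9, v21)
})

test_that("surrogate backend produces an odd saturating cue and runs end to end", {
  th <- seq(-pi / 2, pi / 2, length.out = 61)
  cue <- crossmodal:::surrogate_auditory_cue(th)
  expect_equal(cue, -rev(cue))
  expect_true(all(diff(cue) > 0))
  expect_equal(range(cue), c(-1, 1))

  sim <- fast_sim(auditory = list(backend = "surrogate"))
  tr <- run_trial(trial_config(9, 3, seed = 2, sim = sim))
  expect_equal(nrow(tr$log), 120)
  expect_true(all(abs(tr$log$x_a) <= 1))
})
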