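# shared fixtures: a reduced world for fast closed-loop tests
fast_sim <- function(...) {
  cm_config(world = list(n_steps = 120L), ...)
}

# default filter spec + acoustics, built once per test run
test_spec <- eardrum_filter_spec()
test_params <- acoustic_params()

# noiseless auditory cue at a given bearing through the full periphery
noiseless_cue <- function(bearing, spec = test_spec, params = test_params,
                          calib = calibrate_auditory(spec, params)) {
  w <- crossmodal:::binaural_window(bearing, params)
  auditory_cue(eardrum_filter(list(left = w$left, right = w$right), spec),
               calib)$x_a
}
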