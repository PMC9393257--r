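Package: crossmodal
Title: Crossmodal Synaptic Plasticity for Audio-Visual Cue Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Embodied simulation of reliability-based audio-visual cue
    integration learned through crossmodal synaptic plasticity. A simulated
    differential-drive agent tracks a randomly moving, intermittently
    sounding audio-visual target. Binaural 2.2 kHz tones are transformed
    into an auditory directional cue by a mirrored pair of 4th-order
    band-pass eardrum filters; a geometric visual receptive field yields a
    visual directional cue. A single multisensory neuron fuses the cues
    through synaptic weights adapted online by gated input-correlation
    (differential Hebbian) learning rules, so that the weights come to track
    the relative reliabilities (inverse variances) of the two cues under
    independently manipulated signal-to-noise ratios. Includes the full
    experiment protocols (single trials, multi-trial sessions with weight
    persistence), a maximum-likelihood-estimation control model, robust
    bisquare regression and Welch t-test machinery for comparing the learned
    model against the MLE control, and plain-text logging of all trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
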