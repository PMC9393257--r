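---
title: "Crossmodal plasticity for audio-visual cue integration: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossmodal plasticity for audio-visual cue integration: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmodal)
```

## The model

A simulated differential-drive agent tracks a moving audio-visual target by
rotating on the spot. Two directional cues, each a scalar in $[-1, +1]$
encoding the target's bearing relative to the agent's frontal axis, are fused
by a single multisensory neuron:

$$ v = w_v\,x_v(t) + w_a\,x_a(t), $$

and the fused output $v$ drives the orientation reflex (positive $v$: rotate
clockwise, toward a target on the right). The synaptic weights are adapted
online by two gated crossmodal input-correlation (differential Hebbian)
rules,

$$ \Delta w_a = \mu\, x_a(t)\, \frac{\delta x_v(t)}{\delta t}, \qquad
   \Delta w_v = \mu\, x_v(t)\, \frac{\delta x_a(t)}{\delta t}, $$

with a shared learning rate $\mu = 0.09$ and backward-difference derivative
estimates. $w_a$ is updated only while the target emits sound (irrespective
of visibility); $w_v$ only while the target is inside the visual receptive
field. Each weight is driven by its own modality's instantaneous cue and the
*other* modality's dynamics: a weight therefore stabilizes when the companion
signal is zero or constant in time, which in the tracking task happens when
the target sits at the centre of the receptive fields. There are no
intramodal terms and no weight bounds.

The hypothesis the model embodies is that this purely crossmodal,
correlation-driven plasticity is sufficient for the weights to come to
reflect the *relative reliabilities* (inverse variances) of the two cues —
i.e. to approximate maximum-likelihood-estimation (MLE) cue weighting —
without any explicit representation of reliability. The package provides the
full simulation, the learning protocols, and the statistical machinery for
comparing the learned model with an explicit MLE control.

## Sensory periphery

**Auditory.** The target emits an intermittent 2.2 kHz tone from two
simulated sound sensors separated by $d = 13$ mm. A plane wave from bearing
$\theta$ arrives with interaural phase difference

$$ \delta\phi = \frac{2\pi f\, d \sin\theta}{c}, \qquad c = 340\ \mathrm{m/s}, $$

so the usable phase range is bounded by the $\pm 90^\circ$ extremes (0.36036
rad for a 1.5 kHz tone at 13 mm; `phase_difference()`). The binaural pair is
transformed into a directional cue by a mirrored two-input/two-output
eardrum-filter pair: each output mixes the ipsilateral channel, through a
fractional delay, with the gain-scaled contralateral channel, both passed
through the same 4th-order Butterworth band-pass (1–4 kHz). The cue $x_a$ is
the output power difference in dB, normalized by a calibration constant and
clipped to $[-1, 1]$.

The original biophysical filter coefficients (derived from laser-vibrometry
measurements of a lizard ear) are not publicly available, so the pair is a
constructed surrogate whose parameters were fixed once, analytically and by a
one-off design sweep, to satisfy the properties the original model is
documented to have:

- For a tone at frequency $f$, the power difference is proportional to
  $\sin\psi(f)\,\sin\delta\phi$, where $\psi(f) = 2\pi f D / f_s$ is the
  phase rotation of the contralateral delay of $D$ samples. Solving
  $\psi\cot\psi = -1$ places the peak of the binaural difference response at
  the carrier; a windowed-simulation sweep refined $D$ to 8.3 samples at
  44.1 kHz, giving a peak near 2.2–2.3 kHz while keeping the cue odd and
  strictly monotone in bearing over the frontal semicircle.
- The calibration constant is the maximum $|\Delta P|$ over a noiseless
  181-point bearing sweep (`calibrate_auditory()`), so the cue saturates at
  exactly $\pm 1$ at $\pm 90^\circ$.

A closed-form surrogate backend (`auditory$backend = "surrogate"`,
$x_a = \sin\theta$ with cue-level noise) is available for fast experiments;
all downstream modules are backend-agnostic.

**Visual.** The visual receptive field is $57^\circ$ wide and 4 m deep
(the field of view of a common depth camera). Inside the field the cue is
the bearing mapped linearly onto $[-1, +1]$ ($+1$ at the right boundary);
outside it the cue is *exactly* zero, modelling a target that is not
detected. Noise is never added to an undetected cue, so a zero cue is
informative about detection, not location.

## Noise injection and the SNR axis

Auditory noise is white Gaussian noise added to the *raw sinusoids* before
the periphery, with variance $P/10^{\mathrm{SNR}/10}$ where $P$ is the
measured mean-square power of the clean window (`add_awgn()`). The periphery
performs no explicit denoising, and the integration window is deliberately
short — 44 samples, about two carrier cycles — because power estimation over
a long window *implicitly* averages noise away: at 3 dB the cue noise
standard deviation is about 0.30 with a 44-sample window but only 0.06 with
a 512-sample window. The short window preserves the intended
noise-transmission behaviour of the pathway.

Visual noise is added directly to the cue. The "measured power" convention
is ill-defined for a scalar-per-step cue (it would vanish at the field
centre, where the cue must remain noisy), so the noise variance is referenced
to a fixed power, `noise$ref_power = 0.09`. This constant calibrates the
*relative* noisiness of the two structurally different injection paths: it
was fixed once so that the auditory pathway is the noisier one at equal
assigned SNR — the regime in which the documented weight phenomenology
(visual dominance at equal SNR, reversal only at a large SNR advantage for
audition) is reproduced. It is the one generator constant with no direct
physical anchor, and the single most influential free parameter of the
noise model.

Within each trial the master seed is split into independent substreams
(trajectory, duty cycle, spawn point, auditory noise, visual noise), so any
component can be replayed or varied in isolation and every run is exactly
reproducible.

## World, units and the closed loop

The published description gives target speeds in "m/time step" on a 0–10
scale, a 4 m-deep visual field, and no arena dimensions; these cannot all be
taken literally at once (a target moving metres per step crosses any
plausible arena in a handful of steps and is almost never within visual
range). The package keeps the schedule scales verbatim — along-track speeds
uniform on $[0, 10]$ held for 5–10 steps, cross-track speeds on $[0, 4]$
with random sign held for 0–5 steps, off/on sound intervals of 5–10 and
10–15 steps — and converts schedule speed units to arena metres with
`world$speed_scale` (default 0.005 m per unit per step). The default arena
is 10 m wide; the target spawns at the right edge, 5 m out and about 3 m
ahead (uniformly jittered by ±0.75 m along the edge so that consecutive
trials differ geometrically but every path remains within sensory reach),
and drifts right-to-left past the agent. A 250-step trial lets the target
sweep past the agent's frontal axis. Longer trials were rejected because at
$\mu = 0.09$ they push low-SNR sessions into a weight-growth instability
(large weights amplify noise into the motor loop, the target leaves the
visual field, and the visual weight starves); this is the same instability
that motivates the reduced learning rate $\mu = 0.01$ in the 100-trial
low-SNR protocol.

The agent only rotates. The wheel-speed mapping `agent$motor_gain` (0.0125 m
per step per unit fused output; rotation per step $= 0.15625\,v$ rad) was
chosen by a small design sweep so that the reflex loop is damped for the
weight magnitudes the learning visits: with the raw mapping
$|v_l| = |v_r| = |v|$ and $l = 0.16$ m, one step would rotate by $12.5\,v$
rad and the loop oscillates for any useful weight. The kinematic update
itself is the standard instantaneous-centre-of-curvature form with
$\omega = (v_r - v_l)/l$ and $D = (l/2)(v_r + v_l)/(v_r - v_l)$, with the
equal-speed translation limit handled exactly.

Within each step the order of operations is fixed and documented: sense →
differentiate → update weights → integrate (with the updated weights) → act.

## Learning protocols

`run_session()` runs consecutive trials under one SNR condition without
resetting the weights (initial weights 0.1/0.1 in trial 1, carried over
thereafter); the agent points straight ahead at every trial start.
`run_protocol()` covers the standard designs: visual SNR fixed at 3 dB with
auditory SNR swept over 6–21 dB in 3 dB steps; the mirror image; both SNRs
equal, swept over 3–21 dB (20 trials each); and the 100-trial low-SNR
design at $\mu = 0.01$. Session summaries report end-of-trial weights, the
simplex-normalized weights $w_i/(w_a + w_v)$ — the only normalization
commensurable with the normalized reliabilities — and the per-trial gated
cue variances with their normalized reliabilities
$(1/\sigma_i^2)\big/\sum_j 1/\sigma_j^2$.

Cue variances are computed over the steps where the cue's gate is active
(sound on, target visible): structural zeros from non-detection describe the
duty cycle, not sensory noise. One consequence of embodiment worth knowing:
when one cue is very noisy, the tracking error it injects into the loop
inflates the *measured* variance of both cues, so measured reliabilities
saturate rather than following assigned SNR one-for-one. The same coupling
is visible in the original study's variance figures (non-monotone variance
versus SNR), and it is the main reason normalized weights track normalized
reliabilities with a persistent offset rather than exactly.

## The MLE comparison

`mle_comparison()` implements the control experiment. First
`learn_condition_weights()` runs one 20-trial session per SNR condition used
by the randomized evaluation and records session-end normalized weights
(the model) and session-median normalized reliabilities (the MLE control).
Then 50 evaluation trials are run with learning disabled; before each trial
the condition is drawn — both SNRs equal to one of {3, 9, 12, 15, 18, 21} dB,
or one random modality drawn from that set with the other at 3 dB — and the
trial comprises two independent tracking runs (own trajectory, duty cycle
and noise): one with the learned weights, one with the MLE weights.

Each run yields a per-trial "average relative target location" estimate.
Two operationalizations are provided, because the original description is
ambiguous:

- `"location"`: the signed time average of the fused location signal over
  gated steps. In a closed loop this statistic is nearly useless for model
  comparison: summing the very signal that drives the rotation telescopes
  into (initial heading − final heading)/gain plus target-motion terms, so
  the statistic is pinned by trial geometry and almost independent of cue
  quality. It is kept for completeness and for open-loop uses.
- `"accuracy"` (default): $1 - \operatorname{mean}|$location signal$|$ over
  gated steps, so higher values mean lower localization error — matching the
  interpretation used for the original one-tailed tests. This statistic
  retains condition (reliability) information and is used for the regression
  and the t-tests.

The learned-model estimates are regressed on the MLE estimates with a
first-order polynomial fit by iteratively reweighted least squares with
Tukey bisquare weights (tuning constant 4.685, residuals scaled by
$1.4826 \cdot \mathrm{MAD}$ about zero, convergence at $10^{-8}$ relative
coefficient change or 50 iterations; points beyond the cutoff get exactly
zero weight). $r^2$, SSE and RMSE are reported for the weighted fit, as
robust curve-fitting tools conventionally do. Four one-tailed Welch t-tests
compare each fused model's accuracy against the auditory-only and
visual-only estimates from its own runs; no multiple-testing correction is
applied, matching the original analysis. `variance_comparison()` tabulates
across-trial estimate variances per condition group for the four estimators;
the fused estimators sit below both unisensory ones, and for the MLE mode
the closed form $\sigma_a^2\sigma_v^2/(\sigma_a^2 + \sigma_v^2)$ is the
reference.

Because every trial redraws trajectories, duty cycles and noise
distributions, a single 50-trial replication's $r^2$ scatters by design
(roughly 0.6–0.85 across seeds under the default configuration); the
acceptance script therefore reports the median over 10 independent
replications of the whole experiment (learning plus evaluation).

## What the generator does and does not emulate

The synthetic world reproduces: intermittent sound emission with the stated
duty cycle; random zig-zag target motion with the stated speed and hold
ranges; independent SNR control per modality; phase-difference-based
binaural encoding over the frontal semicircle; exact non-detection zeros
outside the visual field. It does not emulate: distance attenuation,
reverberation or interaural level differences (assumed absent); front-back
ambiguity (bearings beyond ±90° are clamped and flagged, with tracking
always starting frontally); visual appearance, occlusion or
detection/recognition errors; wheel slip or motor dynamics. Passing tests
therefore speak to the plasticity-and-integration mechanism under idealized
sensing, not to performance on real sensor streams.

## Numerical and degenerate-input choices

- Derivatives: backward differences; the first frame of a trial returns 0.
- Cue clipping to $[-1, 1]$ after noise injection keeps the type invariants;
  heavy clipping only occurs at the lowest SNRs.
- `add_awgn()` on an all-zero signal returns it unchanged (silence carries
  no measured power to reference noise against).
- Bearings outside the frontal semicircle clamp the auditory cue at its
  lateral extreme; the event is counted in the trial summary.
- The visual field boundary is closed, with $10^{-9}$ rad of slack against
  rounding.
- Weights are unbounded, as specified; a trial warns (and completes) if a
  weight passes $10^3$.
- The bisquare IRLS keeps the last stable fit if the residual scale
  collapses onto a cluster (fewer than two points would retain weight);
  a zero-variance predictor is an error.
- Trials with no visible step yield no visual-only estimate; the comparison
  uses complete cases per statistic.

## Problem sizes

Default sessions are 20 trials of 250 steps; the low-SNR protocol is 100
trials at $\mu = 0.01$. The packaged comparison uses 16 learning sessions
(one per evaluation condition) and 50 evaluation trials per replication,
with 10 replications in the acceptance script. These sizes were chosen so a
full replication runs in seconds on one core while every session-level claim
is still exercised at its stated trial counts.
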