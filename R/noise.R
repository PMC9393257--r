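#' Add white Gaussian noise at a target SNR
#'
#' Noise variance is set relative to the measured mean-square power of the
#' input (`P / 10^(snr_db / 10)`), mirroring the "measured" signal-power
#' convention. A zero-power input receives no noise, so silence passes
#' through unchanged.
#'
#' @param x numeric sample vector.
#' @param snr_db target signal-to-noise ratio in dB.
#' @param noise optional pre-drawn standard-normal vector of `length(x)`
#'   (used to pair noise realizations across runs); drawn internally when
#'   `NULL`.
#' @return `x` plus scaled noise; the input is not modified.
#' @export
#' @examples
#' y <- add_awgn(sin(seq(0, 10, 0.01)), snr_db = 10)
add_awgn <- function(x, snr_db, noise = NULL) {
  if (length(x) == 0) stop("`x` must be nonempty", call. = FALSE)
  stopifnot_scalar(snr_db, "snr_db")
  p <- mean(x^2)
  if (p == 0) return(x)
  sdn <- sqrt(p / 10^(snr_db / 10))
  if (is.null(noise)) noise <- rnorm(length(x))
  x + sdn * noise
}

# noise sd for scalar-per-step cues. ref_power is a fixed reference rather
# than the instantaneous cue power (which would vanish at the field centre);
# its default calibrates the relative noisiness of the two pathways at equal
# assigned SNR so the weight-dominance reversal sits near the observed
# +15 dB SNR difference (see the package vignette).
cue_noise_sd <- function(snr_db, ref_power = 0.09) {
  sqrt(ref_power / 10^(snr_db / 10))
}

#' Unbiased sample variance of a cue series
#'
#' @param series numeric vector, length >= 2.
#' @return sample variance (n - 1 denominator).
#' @export
cue_variance <- function(series) {
  if (length(series) < 2L)
    stop("need at least two values to estimate a variance", call. = FALSE)
  stats::var(series)
}

#' Normalized cue reliabilities
#'
#' Reliability of a cue is the inverse of its variance; normalized
#' reliabilities are each cue's share of the summed inverse variances:
#' `rel_a = (1/var_a) / (1/var_a + 1/var_v)`, and `rel_v = 1 - rel_a`.
#'
#' @param var_a auditory cue variance (> 0).
#' @param var_v visual cue variance (> 0).
#' @return a list of class `reliability_pair` with `var_a`, `var_v`,
#'   `rel_a_norm`, `rel_v_norm`.
#' @export
#' @examples
#' normalized_reliabilities(1, 3)  # (0.75, 0.25)
normalized_reliabilities <- function(var_a, var_v) {
  stopifnot_scalar(var_a, "var_a", positive = TRUE)
  stopifnot_scalar(var_v, "var_v", positive = TRUE)
  rel_a <- (1 / var_a) / (1 / var_a + 1 / var_v)
  structure(list(var_a = var_a, var_v = var_v,
                 rel_a_norm = rel_a, rel_v_norm = 1 - rel_a),
            class = "reliability_pair")
}
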