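# Synthetic shear-stress signals with known spectral content: a constant
# level, prescribed harmonics of a fundamental frequency, optional per-beat
# amplitude jitter (a nonperiodic component with beat-to-beat structure) and
# additive white noise.  These are the controlled stand-ins for simulated
# wall shear stress series used to validate the decomposition stage.

#' Specify a synthetic shear-stress signal
#'
#' @param constant constant (time-average) level.
#' @param harmonics matrix-like with columns `k` (positive integer harmonic
#'   index), `amplitude`, `phase` (radians); may be an empty data frame.
#' @param f1 fundamental frequency.
#' @param n_beats number of beats (>= 1).
#' @param samples_per_beat samples per beat; must be at least 4 times the
#'   highest harmonic index (Nyquist with margin).
#' @param noise_sd per-sample Gaussian noise standard deviation.
#' @param jitter_frac per-beat multiplicative amplitude jitter fraction.
#' @param seed RNG seed.
#' @return object of class `signal_spec`.
#' @export
signal_spec <- function(constant = 0,
                        harmonics = data.frame(k = 1, amplitude = 1, phase = 0),
                        f1 = 1, n_beats = 8, samples_per_beat = 64,
                        noise_sd = 0, jitter_frac = 0, seed = 1) {
  harmonics <- as.data.frame(harmonics)
  if (nrow(harmonics) > 0) {
    stopifnot(all(harmonics$k == round(harmonics$k)), all(harmonics$k >= 1))
    if (samples_per_beat < 4 * max(harmonics$k)) {
      stop("spec error: samples_per_beat must be >= 4 x highest harmonic ",
           "index (Nyquist margin)")
    }
  }
  stopifnot(f1 > 0, n_beats >= 1, noise_sd >= 0, jitter_frac >= 0)
  structure(list(
    constant = constant, harmonics = harmonics, f1 = f1,
    n_beats = as.integer(n_beats),
    samples_per_beat = as.integer(samples_per_beat),
    noise_sd = noise_sd, jitter_frac = jitter_frac, seed = as.integer(seed)
  ), class = "signal_spec")
}

#' Generate a synthetic shear-stress time series
#'
#' `value(t) = constant + sum_k amplitude_k sin(2 pi k f1 t + phase_k)`,
#' with per-beat amplitude jitter and per-sample noise when requested.
#' Exactly `n_beats * samples_per_beat` samples, uniformly spaced starting
#' at `t = 0`.
#'
#' @param spec a [signal_spec()].
#' @return data.frame with columns `time`, `value`, plus attribute
#'   `"clean"` holding the noiseless jitter-free signal.
#' @export
make_signal <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  Tb <- 1 / spec$f1
  n <- spec$n_beats * spec$samples_per_beat
  time <- (seq_len(n) - 1) * Tb / spec$samples_per_beat
  clean <- rep(spec$constant, n)
  if (nrow(spec$harmonics) > 0) {
    for (r in seq_len(nrow(spec$harmonics))) {
      clean <- clean + spec$harmonics$amplitude[r] *
        sin(2 * pi * spec$harmonics$k[r] * spec$f1 * time +
            spec$harmonics$phase[r])
    }
  }
  value <- clean
  old <- .vm_set_seed(spec$seed)
  on.exit(.vm_restore_seed(old), add = TRUE)
  if (spec$jitter_frac > 0 && nrow(spec$harmonics) > 0) {
    beat <- rep(seq_len(spec$n_beats), each = spec$samples_per_beat)
    jit <- 1 + spec$jitter_frac * stats::rnorm(spec$n_beats)
    osc <- numeric(n)
    for (r in seq_len(nrow(spec$harmonics))) {
      osc <- osc + spec$harmonics$amplitude[r] *
        sin(2 * pi * spec$harmonics$k[r] * spec$f1 * time +
            spec$harmonics$phase[r])
    }
    value <- spec$constant + osc * jit[beat]
  }
  if (spec$noise_sd > 0) {
    value <- value + stats::rnorm(n, 0, spec$noise_sd)
  }
  out <- data.frame(time = time, value = value)
  attr(out, "clean") <- clean
  out
}
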