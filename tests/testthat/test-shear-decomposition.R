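# Shear-stress decomposition: exact Fourier recovery, phase-average
# behavior under noise, nonperiodic RMS calibration, the variance identity,
# linearity, shift invariance and spatial profile operations.

test_that("phase average reproduces a pure sine and a constant exactly", {
  t <- (0:191) / 64
  v <- sin(2 * pi * t)
  pa <- phase_average(t, v, 1)
  expect_lt(max(abs(pa$curve - sin(2 * pi * pa$phase))), 1e-12)
  pc <- phase_average(t, rep(7, length(t)), 1)
  expect_true(all(abs(pc$curve - 7) < 1e-12))
})

test_that("harmonic amplitudes recover a constructed 2-harmonic curve", {
  t <- (0:255) / 64
  v <- 2 + 3 * sin(2 * pi * t) + 0.5 * sin(4 * pi * t)
  ha <- harmonic_amplitudes(phase_average(t, v, 1), 3)
  expect_equal(ha$tau0, 2, tolerance = 1e-12)
  expect_equal(ha$tau_k[1], 3, tolerance = 1e-12)
  expect_equal(ha$tau_k[2], 0.5, tolerance = 1e-12)
  expect_lt(ha$tau_k[3], 1e-12)

  hc <- harmonic_amplitudes(phase_average(t, rep(7, 256), 1), 3)
  expect_equal(hc$tau0, 7)
  expect_true(all(hc$tau_k < 1e-12))

  expect_error(harmonic_amplitudes(phase_average(t, v, 1, bins = 16), 8),
               "aliasing")
})

test_that("a random curve is reconstructed from its full harmonic set", {
  set.seed(21)
  curve <- rnorm(32)
  ha <- harmonic_amplitudes(curve, 15)
  ph <- (0:31) / 32
  rec <- rep(ha$tau0, 32)
  for (k in 1:15) {
    rec <- rec + ha$tau_k[k] * sin(2 * pi * k * ph + ha$phase_k[k])
  }
  # even bin count: the Nyquist mode is not in the k <= 15 set
  co <- stats::fft(curve) / 32
  nyq <- Re(co[17]) * cos(2 * pi * 16 * ph)
  expect_lt(max(abs(curve - rec - nyq)), 1e-10)
})

test_that("phase-average noise suppression scales as sigma/sqrt(N)", {
  devs <- vapply(1:12, function(s) {
    sp <- signal_spec(constant = 0,
                      harmonics = data.frame(k = 1, amplitude = 1, phase = 0),
                      n_beats = 25, samples_per_beat = 32,
                      noise_sd = 0.2, seed = 100 + s)
    sig <- make_signal(sp)
    pa <- phase_average(sig$time, sig$value, 1)
    sqrt(mean((pa$curve - sin(2 * pi * pa$phase))^2))
  }, numeric(1))
  expect_equal(mean(devs), 0.2 / sqrt(25), tolerance = 0.15)
})

test_that("nonperiodic RMS matches the decomposition-of-variance oracle", {
  # exactly periodic series: tau' ~ 0
  t <- (0:255) / 32
  v <- 1 + 2 * sin(2 * pi * t + 0.4)
  pa <- phase_average(t, v, 1)
  expect_lt(nonperiodic_rms(t, v, pa), 1e-12)
  # periodic + noise sigma over N beats: tau' ~ sigma sqrt(1 - 1/N)
  vals <- vapply(1:10, function(s) {
    sp <- signal_spec(constant = 1,
                      harmonics = data.frame(k = 1, amplitude = 2, phase = 0.3),
                      n_beats = 16, samples_per_beat = 32,
                      noise_sd = 0.1, seed = 200 + s)
    sig <- make_signal(sp)
    nonperiodic_rms(sig$time, sig$value,
                    phase_average(sig$time, sig$value, 1))
  }, numeric(1))
  expect_equal(mean(vals), 0.1 * sqrt(1 - 1 / 16), tolerance = 0.05)
})

test_that("variance identity holds for band-limited nonperiodic signals", {
  sp <- signal_spec(constant = 1.5,
                    harmonics = data.frame(k = c(1, 2),
                                           amplitude = c(2, 0.7),
                                           phase = c(0.3, -1)),
                    n_beats = 16, samples_per_beat = 32,
                    jitter_frac = 0.15, seed = 11)
  sig <- make_signal(sp)
  pa <- phase_average(sig$time, sig$value, 1, bins = 32)
  ha <- harmonic_amplitudes(pa, 15)
  tn <- nonperiodic_rms(sig$time, sig$value, pa)
  lhs <- mean(sig$value^2)
  rhs <- ha$tau0^2 + 0.5 * sum(ha$tau_k^2) + tn^2
  expect_lt(abs(lhs - rhs) / lhs, 1e-6)
})

test_that("decomposition is linear and tau' is invariant to beat shifts", {
  sp <- signal_spec(constant = 1,
                    harmonics = data.frame(k = 1, amplitude = 2, phase = 0),
                    n_beats = 8, samples_per_beat = 32,
                    jitter_frac = 0.2, seed = 3)
  sig <- make_signal(sp)
  a <- -1.7
  b <- 0.9
  pa1 <- phase_average(sig$time, sig$value, 1)
  pa2 <- phase_average(sig$time, a * sig$value + b, 1)
  h1 <- harmonic_amplitudes(pa1, 3)
  h2 <- harmonic_amplitudes(pa2, 3)
  expect_equal(h2$tau0, a * h1$tau0 + b, tolerance = 1e-12)
  expect_equal(h2$tau_k, abs(a) * h1$tau_k, tolerance = 1e-10)
  expect_equal(nonperiodic_rms(sig$time, a * sig$value + b, pa2),
               abs(a) * nonperiodic_rms(sig$time, sig$value, pa1),
               tolerance = 1e-10)
  # circular shift by whole beats
  shifted <- c(sig$value[-(1:32)], sig$value[1:32])
  pas <- phase_average(sig$time, shifted, 1)
  expect_equal(nonperiodic_rms(sig$time, shifted, pas),
               nonperiodic_rms(sig$time, sig$value, pa1), tolerance = 1e-10)
})

test_that("trailing partial periods are discarded with a warning", {
  t <- (0:99) / 32
  v <- sin(2 * pi * t)
  expect_warning(phase_average(t, v, 1), "partial period")
  expect_error(phase_average((0:40) / 32, sin(2 * pi * (0:40) / 32), 1),
               "at least 2 complete periods")
})

test_that("spatial profiles: flat input gives flat output, normalization has mean 1", {
  sp <- signal_spec(constant = 0.5,
                    harmonics = data.frame(k = 1, amplitude = 2, phase = 0),
                    n_beats = 4, samples_per_beat = 32)
  sig <- make_signal(sp)
  rec <- list(time = sig$time,
              tau = matrix(sig$value, nrow(sig), 5),
              stations = seq(0, 4, length.out = 5),
              period = 1)
  dec <- spatial_profiles(rec, K = 2)
  expect_lt(diff(range(dec$tau0)), 1e-12)
  expect_lt(diff(range(dec$tau_k[1, ])), 1e-12)
  expect_equal(mean(dec$normalized$tau_k[1, ]), 1, tolerance = 1e-12)
  expect_true(all(abs(gradient_tau1(dec, periodic = FALSE)) < 1e-10))
})

test_that("gradient of tau1 handles ramps and nonuniform grids", {
  dec <- structure(list(
    stations = c(0, 1, 2, 3.5, 5),
    tau_k = matrix(c(0, 2, 4, 7, 10), 1)
  ), class = "wss_decomposition")
  g <- gradient_tau1(dec, periodic = FALSE)
  expect_equal(g, rep(2, 5), tolerance = 1e-12)
})

test_that("the autocorrelation period estimator finds the beat period", {
  sp <- signal_spec(constant = 1,
                    harmonics = data.frame(k = c(1, 2),
                                           amplitude = c(2, 0.5),
                                           phase = c(0, 1)),
                    n_beats = 24, samples_per_beat = 40,
                    noise_sd = 0.1, seed = 5)
  sig <- make_signal(sp)
  expect_equal(estimate_period(sig$time, sig$value), 1, tolerance = 0.02)
})
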