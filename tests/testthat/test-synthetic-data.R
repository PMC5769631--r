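# Synthetic-data generators: spectral content of signals, determinism,
# noise calibration; phantom ground truth, determinism, and brute-force
# voxel recovery of the gap.

test_that("noiseless signals are the deterministic sampled sum", {
  sp <- signal_spec(constant = 2,
                    harmonics = data.frame(k = c(1, 2),
                                           amplitude = c(3, 0.5),
                                           phase = c(0, 0)),
                    n_beats = 2, samples_per_beat = 32)
  sig <- make_signal(sp)
  expect_equal(nrow(sig), 64)
  expect_equal(sig$value,
               2 + 3 * sin(2 * pi * sig$time) + 0.5 * sin(4 * pi * sig$time),
               tolerance = 1e-13)

  zero <- make_signal(signal_spec(constant = 0,
                                  harmonics = data.frame(k = integer(),
                                                         amplitude = numeric(),
                                                         phase = numeric()),
                                  n_beats = 1, samples_per_beat = 16))
  expect_true(all(zero$value == 0))
})

test_that("Nyquist violations and bad harmonics are spec errors", {
  expect_error(signal_spec(harmonics = data.frame(k = 10, amplitude = 1,
                                                  phase = 0),
                           samples_per_beat = 16),
               "Nyquist")
  expect_error(signal_spec(harmonics = data.frame(k = 0.5, amplitude = 1,
                                                  phase = 0)))
})

test_that("same seed gives identical noise, different seeds differ", {
  sp1 <- signal_spec(noise_sd = 0.2, seed = 4, n_beats = 2)
  sp2 <- signal_spec(noise_sd = 0.2, seed = 5, n_beats = 2)
  expect_identical(make_signal(sp1)$value, make_signal(sp1)$value)
  expect_false(identical(make_signal(sp1)$value, make_signal(sp2)$value))
})

test_that("noise variance and sample mean behave as specified", {
  # variance of the residual after subtracting the clean signal ~ sigma^2
  devs <- vapply(1:8, function(s) {
    sp <- signal_spec(constant = 1, noise_sd = 0.1, seed = s, n_beats = 64,
                      samples_per_beat = 16)
    sig <- make_signal(sp)
    stats::var(sig$value - attr(sig, "clean"))
  }, numeric(1))
  expect_equal(mean(devs), 0.01, tolerance = 0.1)
  # integer beats: sample mean = constant within O(noise/sqrt(N))
  sp <- signal_spec(constant = 2.5, noise_sd = 0.1, seed = 2, n_beats = 64,
                    samples_per_beat = 32)
  sig <- make_signal(sp)
  expect_equal(mean(sig$value), 2.5,
               tolerance = 5 * 0.1 / sqrt(nrow(sig)) / 2.5)
})

test_that("phantom ground truth carries the prescribed shortening", {
  pair <- small_phantom_pair(gap1 = 40, gap2 = 28)
  g1 <- pair$t1$ground_truth$gap_length_um
  g2 <- pair$t2$ground_truth$gap_length_um
  expect_equal((g2 - g1) / g1, -0.30, tolerance = 1e-12)
  pair0 <- small_phantom_pair(gap1 = 35, gap2 = 35)
  expect_equal(pair0$t2$ground_truth$gap_length_um -
                 pair0$t1$ground_truth$gap_length_um, 0)
})

test_that("phantoms are seed-deterministic with red only in the bands", {
  a <- make_phantom(small_phantom_pair(noise_sd = 3, seed = 7)$spec, 1)
  b <- make_phantom(small_phantom_pair(noise_sd = 3, seed = 7)$spec, 1)
  expect_identical(a$green, b$green)
  expect_identical(a$red, b$red)
  expect_gt(sum(a$red > 100), 0)
  # green shell is labeled along the whole tube, red only in the bands
  expect_gt(sum(a$green > 100), 2 * sum(a$red > 100))
})

test_that("a brute-force voxel scan recovers the gap within one voxel", {
  pair <- small_phantom_pair(noise_sd = 0)
  ph <- pair$t1
  d <- dim(ph$red)
  gx <- ph$origin[1] + (seq_len(d[1]) - 1) * ph$spacing[1]
  # scan along the tube at the shell (z = semi-axis a above the axis)
  kz <- round((12 - ph$origin[3]) / ph$spacing[3]) + 1
  jy <- round((0 - ph$origin[2]) / ph$spacing[2]) + 1
  prof <- ph$red[, jy, kz]
  thr <- 0.5 * max(prof)
  above <- prof > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  bi <- which(r$values)
  expect_equal(length(bi), 2)
  # sub-voxel edge interpolation on the two inner edges
  i1 <- ends[bi[1]]
  e1 <- gx[i1] + (prof[i1] - thr) / (prof[i1] - prof[i1 + 1]) * ph$spacing[1]
  i2 <- starts[bi[2]]
  e2 <- gx[i2] - (prof[i2] - thr) / (prof[i2] - prof[i2 - 1]) * ph$spacing[1]
  expect_equal(e2 - e1, ph$ground_truth$gap_length_um,
               tolerance = ph$spacing[1] / 40)
})

test_that("phantom TIFF round-trips through the sidecar metadata", {
  pair <- small_phantom_pair(noise_sd = 2)
  tmp <- file.path(tempdir(), "ph.tiff")
  write_phantom_tiff(pair$t1, tmp)
  back <- read_phantom_tiff(tmp)
  expect_equal(dim(back$green), dim(pair$t1$green))
  expect_equal(back$green, pair$t1$green, tolerance = 1e-5)
  expect_equal(back$spacing, pair$t1$spacing)
  truth <- utils::read.csv(file.path(tempdir(), "ph_truth.csv"))
  expect_equal(truth$gap_length_um, 40)
  unlink(file.path(tempdir(), c("ph.tiff", "ph.json", "ph_truth.csv")))
})
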