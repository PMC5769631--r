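# Simulator bookkeeping and statistics: trivial no-motion case, seeding
# determinism, concentration profiles against area oracles, and
# depleted-region detection.

test_that("no wall motion and no cells give zero stress and flux", {
  geom <- tube_geometry()
  mot <- wall_motion(geom, amplitude = function(x) 0 * x,
                     phase = function(x) 0 * x)
  cfg <- sim_config(geom, mot, n_rbc = 0, n_per_wall = 32,
                    steps_per_beat = 8, n_beats = 2, discard_beats = 1,
                    samples_per_beat = 4, n_stations = 8)
  sim <- run_heart_sim(cfg)
  expect_lt(max(abs(sim$tau_u), na.rm = TRUE), 1e-8)
  expect_lt(max(abs(sim$flux), na.rm = TRUE), 1e-8)
})

test_that("seeding is reproducible and respects the region and walls", {
  geom <- tube_geometry()
  mot <- wall_motion(geom)
  p <- membrane_params(n_nodes = 16, semi_axes = c(0.35, 0.18))
  s1 <- seed_membranes(p, mot, 6, seed = 3)
  s2 <- seed_membranes(p, mot, 6, seed = 3)
  s3 <- seed_membranes(p, mot, 6, seed = 4)
  expect_identical(lapply(s1, `[[`, "x"), lapply(s2, `[[`, "x"))
  expect_false(identical(lapply(s1, `[[`, "x"), lapply(s3, `[[`, "x")))
  reg <- geom$segments$atrium
  for (s in s1) {
    # centers lie in the region; nodes may overhang by at most a semi-axis
    expect_true(all(s$x > reg[1] - 0.4 & s$x < reg[2] + 0.4))
    expect_true(all(abs(s$y) < geom$h0(s$x)))
  }
})

fake_sim <- function(outlines, L = 8, n_rbc = 1) {
  geom <- tube_geometry(length = L)
  structure(list(
    config = list(geometry = geom, n_rbc = n_rbc),
    retained = rep(TRUE, length(outlines)),
    outlines = outlines
  ), class = "heart_sim")
}

test_that("concentration of one stationary cell integrates to its area", {
  p <- membrane_params(n_nodes = 32, semi_axes = c(0.5, 0.25))
  st <- membrane_state(p, center = c(3.1, 0))
  sim <- fake_sim(list(list(cbind(st$x, st$y))))
  pr <- concentration_profile(sim, bins = 40)
  tot <- sum(pr$density * (pr$upper - pr$lower))
  expect_equal(tot, valvemorph:::.vm_shoelace(st$x, st$y), tolerance = 1e-6)
  # within 1% of the smooth ellipse area at this node count
  expect_equal(tot, pi * 0.5 * 0.25, tolerance = 0.01)
  # localized to the bins the cell overlaps (roundoff elsewhere)
  expect_lt(max(abs(pr$density[pr$x < 2.4 | pr$x > 3.8])), 1e-12)
})

test_that("cells crossing the periodic boundary keep their full area", {
  p <- membrane_params(n_nodes = 32, semi_axes = c(0.4, 0.2))
  st <- membrane_state(p, center = c(0.05, 0))
  sim <- fake_sim(list(list(cbind(st$x, st$y))))
  pr <- concentration_profile(sim, bins = 32)
  tot <- sum(pr$density * (pr$upper - pr$lower))
  expect_equal(tot, valvemorph:::.vm_shoelace(st$x, st$y), tolerance = 1e-6)
})

test_that("uniform random cell placement gives a flat profile", {
  p <- membrane_params(n_nodes = 16, semi_axes = c(0.25, 0.25))
  set.seed(8)
  outl <- lapply(1:60, function(i) {
    st <- membrane_state(p, center = c(runif(1, 0, 8), runif(1, -0.4, 0.4)))
    list(cbind(st$x, st$y))
  })
  sim <- fake_sim(outl)
  pr <- concentration_profile(sim, bins = 8)
  # binomial sampling error band: each bin sees ~ n * w/L cells
  expect_lt(stats::sd(pr$density) / mean(pr$density), 0.5)
  expect_gt(min(pr$density), 0)
})

test_that("depleted regions are the maximal below-threshold intervals", {
  prof <- data.frame(x = (1:10) - 0.5, lower = 0:9, upper = 1:10,
                     density = rep(1, 10))
  expect_equal(nrow(depleted_regions(prof, 0.5)), 0)
  prof$density[4] <- 0
  d1 <- depleted_regions(prof, 0.5)
  expect_equal(nrow(d1), 1)
  expect_equal(c(d1$start, d1$end), c(3, 4))
  prof$density[c(4, 5)] <- 0
  prof$density[9] <- 0.2
  d2 <- depleted_regions(prof, 0.6)
  expect_equal(nrow(d2), 2)
  expect_equal(d2$start, c(3, 8))
  expect_equal(d2$end, c(5, 9))
})

test_that("wss_record keeps only retained beats with uniform spacing", {
  sim <- test_norbc_sim()
  rec <- wss_record(sim, "upper")
  expect_equal(nrow(rec$tau),
               sim$config$samples_per_beat *
                 (sim$config$n_beats - sim$config$discard_beats))
  expect_lt(diff(range(diff(rec$time))), 1e-10)
  expect_equal(rec$n_beats, 4)
})
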