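# Membrane mechanics: the elastic force is the exact negative gradient of
# the discrete energy, is translation/rotation-free, relaxes shapes
# monotonically, and refines at second order; repulsion obeys Newton's
# third law; reparameterization preserves area and uniformizes spacing.

test_that("a circle at its reference radius with k_b = 0 is force-free", {
  p <- membrane_params(k_s = 5, k_b = 0, n_nodes = 32,
                       semi_axes = c(0.5, 0.5))
  st <- membrane_state(p)
  expect_lt(max(abs(elastic_forces(st))), 1e-12)
})

test_that("elastic forces are the negative energy gradient (FD oracle)", {
  p <- membrane_params(n_nodes = 24)
  st <- membrane_state(p, center = c(1, 0.2), angle = 0.4)
  set.seed(3)
  st$x <- st$x + rnorm(24, 0, 0.02)
  st$y <- st$y + rnorm(24, 0, 0.02)
  F <- elastic_forces(st)
  h <- 1e-6
  for (i in c(1, 7, 13, 20)) {
    for (d in 1:2) {
      sp <- st
      sm <- st
      if (d == 1) {
        sp$x[i] <- sp$x[i] + h
        sm$x[i] <- sm$x[i] - h
      } else {
        sp$y[i] <- sp$y[i] + h
        sm$y[i] <- sm$y[i] - h
      }
      fd <- -(valvemorph:::membrane_energy(sp) -
                valvemorph:::membrane_energy(sm)) / (2 * h)
      expect_equal(unname(F[i, d]), fd, tolerance = 1e-4)
    }
  }
})

test_that("force sets carry no net force or torque", {
  p <- membrane_params(n_nodes = 32)
  set.seed(9)
  st <- membrane_state(p, center = c(2, -0.1), angle = 1.1)
  st$x <- st$x + rnorm(32, 0, 0.03)
  st$y <- st$y + rnorm(32, 0, 0.03)
  F <- elastic_forces(st)
  sc <- max(abs(F))
  expect_lt(max(abs(colSums(F))) / sc, 1e-12)
  expect_lt(abs(sum(st$x * F[, 2] - st$y * F[, 1])) / sc, 1e-12)
})

test_that("quiescent relaxation monotonically decreases the energy", {
  p <- membrane_params(k_s = 5, k_b = 0.02, n_nodes = 32,
                       semi_axes = c(0.5, 0.5))
  st <- membrane_state(p)
  set.seed(5)
  st$x <- st$x + rnorm(32, 0, 0.03)
  st$y <- st$y + rnorm(32, 0, 0.03)
  E <- valvemorph:::membrane_energy(st)
  mono <- TRUE
  for (it in 1:300) {
    F <- elastic_forces(st)
    st$x <- st$x + 0.002 * F[, 1]
    st$y <- st$y + 0.002 * F[, 2]
    En <- valvemorph:::membrane_energy(st)
    if (En > E + 1e-12) mono <- FALSE
    E <- En
  }
  expect_true(mono)
})

test_that("repulsion is zero beyond cutoff and pairwise antisymmetric", {
  p <- membrane_params(n_nodes = 16, repulsion_cutoff = 0.08,
                       repulsion_strength = 5,
                       semi_axes = c(0.2, 0.1))
  far <- list(membrane_state(p, center = c(1, 0)),
              membrane_state(p, center = c(3, 0)))
  Ff <- repulsion_forces(far, Lp = 8)
  expect_true(all(vapply(Ff, function(m) all(m == 0), logical(1))))

  near <- list(membrane_state(p, center = c(1, 0.12)),
               membrane_state(p, center = c(1, -0.13)))
  Fn <- repulsion_forces(near, Lp = 8)
  tot <- colSums(Fn[[1]]) + colSums(Fn[[2]])
  expect_lt(max(abs(tot)), 1e-12)
  expect_gt(max(abs(Fn[[1]])), 0)
})

test_that("reparameterization preserves area and uniformizes spacing", {
  p <- membrane_params(n_nodes = 32, semi_axes = c(0.5, 0.5))
  st <- membrane_state(p)
  set.seed(11)
  th <- sort(runif(32, 0, 2 * pi))
  st$x <- 0.5 * cos(th)
  st$y <- 0.5 * sin(th)
  A0 <- valvemorph:::.vm_shoelace(st$x, st$y)
  st2 <- reparameterize(st)
  A1 <- valvemorph:::.vm_shoelace(st2$x, st2$y)
  expect_lt(abs(A1 / A0 - 1), 1e-6)
  l <- sqrt(diff(c(st2$x, st2$x[1]))^2 + diff(c(st2$y, st2$y[1]))^2)
  expect_lt((max(l) - min(l)) / mean(l), 0.01)

  # an ellipse keeps its shoelace area too
  pe <- membrane_params(n_nodes = 32)
  se <- membrane_state(pe)
  Ae0 <- valvemorph:::.vm_shoelace(se$x, se$y)
  se2 <- reparameterize(se)
  expect_lt(abs(valvemorph:::.vm_shoelace(se2$x, se2$y) / Ae0 - 1), 1e-6)
})

test_that("doubling the node count refines the force density at O(h^2)", {
  # smooth perturbed ellipse sampled so that every node of the coarse curve
  # coincides with every other node of the fine one
  shape <- function(n) {
    tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    x <- 0.6 * cos(tt) + 0.02 * cos(2 * tt)
    y <- 0.3 * sin(tt) + 0.02 * sin(3 * tt)
    p <- membrane_params(k_s = 4, k_b = 0.05, n_nodes = max(n, 16),
                         semi_axes = c(0.6, 0.3))
    st <- membrane_state(p)
    st$x <- x
    st$y <- y
    l <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
    # reference metrics from the analytic rest ellipse at matching density
    rt <- seq(0, 2 * pi, length.out = 8 * n + 1)
    rx <- 0.6 * cos(rt)
    ry <- 0.3 * sin(rt)
    per <- sum(sqrt(diff(rx)^2 + diff(ry)^2))
    st$l0 <- rep(per / n, n)
    st$ds0 <- rep(per / n, n)
    F <- elastic_forces(st)
    sweep(F, 1, st$ds0, "/") # force density
  }
  f1 <- shape(32)
  f2 <- shape(64)
  f3 <- shape(128)
  d1 <- max(abs(f2[seq(1, 64, 2), ] - f1))
  d2 <- max(abs(f3[seq(1, 128, 2), ] - f2))
  expect_lt(d2, d1 / 2.5)
})

test_that("degenerate and self-intersecting inputs raise geometry errors", {
  p <- membrane_params(n_nodes = 16, semi_axes = c(0.3, 0.15))
  st <- membrane_state(p)
  st$x[2] <- st$x[1]
  st$y[2] <- st$y[1]
  expect_error(elastic_forces(st), "degenerate")

  fig8 <- membrane_state(p)
  th <- seq(0, 2 * pi, length.out = 17)[-17] + 0.19
  fig8$x <- 0.3 * sin(2 * th)
  fig8$y <- 0.15 * sin(th)
  expect_error(reparameterize(fig8), "self-intersecting")
})
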