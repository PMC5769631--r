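# Shared fixtures: small meshes, phantoms and cached simulation runs.
# Simulations are memoized per test session so acceptance checks can share
# runs.

.vm_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .vm_cache)) {
    assign(key, force(expr), envir = .vm_cache)
  }
  get(key, envir = .vm_cache)
}

# straight rigid channel mesh of half-height h (static walls)
straight_mesh <- function(n = 64, h = 1, Lp = 8, eps_factor = 1.5) {
  xg <- (seq_len(n) - 0.5) * Lp / n
  valvemorph:::.vm_mesh_from_walls(xg, rep(h, n), xg, rep(-h, n), Lp,
                                   eps_factor = eps_factor)
}

# small straight-tube phantom pair (noise-free unless asked)
small_phantom_pair <- function(noise_sd = 0, gap1 = 40, gap2 = 28,
                               seed = 1, ...) {
  straight <- cbind(seq(0, 150, length.out = 7), rep(0, 7), rep(0, 7))
  sp <- phantom_spec(centerline = straight, noise_sd = noise_sd,
                     gap1 = gap1, gap2 = gap2, seed = seed, ...)
  list(spec = sp, t1 = make_phantom(sp, 1), t2 = make_phantom(sp, 2))
}

true_centerline <- function(ph) {
  gt <- ph$ground_truth
  structure(list(points = gt$centerline$points, s = gt$centerline$s,
                 tangent = gt$centerline$tangent,
                 n1 = gt$frames$n1, n2 = gt$frames$n2),
            class = "tube_centerline")
}

# the package's reference no-RBC heart simulation at test scale
test_norbc_sim <- function() {
  cached("norbc", {
    geom <- tube_geometry()
    cfg <- sim_config(geom, wall_motion(geom), n_rbc = 0,
                      n_per_wall = 72, steps_per_beat = 72,
                      n_beats = 6, discard_beats = 2,
                      samples_per_beat = 36, n_stations = 32)
    run_heart_sim(cfg)
  })
}

# reduced-size RBC simulation used for the cell-number sweeps
test_rbc_sim <- function(n_rbc, n_per_wall = 64, steps_per_beat = 60,
                         n_beats = 3, discard_beats = 1) {
  cached(paste0("rbc", n_rbc), {
    geom <- tube_geometry()
    cfg <- sim_config(geom, wall_motion(geom),
                      membrane = membrane_params(n_nodes = 20),
                      n_rbc = n_rbc, seed = 42,
                      n_per_wall = n_per_wall,
                      steps_per_beat = steps_per_beat,
                      n_beats = n_beats, discard_beats = discard_beats,
                      samples_per_beat = 30, n_stations = 32,
                      seeding_region = rbind(geom$segments$atrium,
                                             geom$segments$ventricle))
    run_heart_sim(cfg)
  })
}
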