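# Time integration of the coupled wall/membrane Stokes system over many
# beats, with recording of wall shear stress at axial stations, channel
# fluxes, membrane trajectories and red-blood-cell concentration statistics.
#
# Explicit predictor-corrector (Heun) stepping: each stage rebuilds the wall
# mesh at the stage time, solves the wall mobility system with the known
# membrane forces, and evaluates membrane node velocities from the full
# superposition.  All randomness (cell seeding) flows from the config seed,
# so identical configs reproduce records bit-identically.

#' Simulation configuration
#'
#' @param geometry a [tube_geometry()].
#' @param motion a [wall_motion()] on the same geometry.
#' @param membrane a [membrane_params()].
#' @param n_rbc number of red blood cells.
#' @param seed integer seed controlling cell seeding.
#' @param n_per_wall wall collocation points per wall.
#' @param steps_per_beat time steps per beat period.
#' @param n_beats total beats simulated.
#' @param discard_beats initial transient beats excluded from statistics.
#' @param samples_per_beat recording cadence (must divide `steps_per_beat`).
#' @param n_stations number of axial shear-stress stations (uniform grid).
#' @param eps_factor regularization length in collocation spacings.
#' @param reparam_every membrane reparameterization interval (steps).
#' @param seeding_region axial interval for initial cell placement
#'   (default: the atrial segment).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(geometry = tube_geometry(),
                       motion = wall_motion(geometry),
                       membrane = membrane_params(),
                       n_rbc = 0, seed = 1,
                       n_per_wall = 128, steps_per_beat = 200,
                       n_beats = 8, discard_beats = 2,
                       samples_per_beat = 50, n_stations = 32,
                       eps_factor = 1.5, reparam_every = 20,
                       seeding_region = NULL) {
  stopifnot(inherits(geometry, "tube_geometry"),
            inherits(motion, "wall_motion"),
            n_rbc >= 0, n_beats > discard_beats,
            steps_per_beat %% samples_per_beat == 0)
  structure(list(
    geometry = geometry, motion = motion, membrane = membrane,
    n_rbc = as.integer(n_rbc), seed = as.integer(seed),
    n_per_wall = as.integer(n_per_wall),
    steps_per_beat = as.integer(steps_per_beat),
    n_beats = as.integer(n_beats),
    discard_beats = as.integer(discard_beats),
    samples_per_beat = as.integer(samples_per_beat),
    n_stations = as.integer(n_stations),
    eps_factor = eps_factor,
    reparam_every = as.integer(reparam_every),
    seeding_region = seeding_region
  ), class = "sim_config")
}

# membrane states -> solver source sets (point forces at nodes)
.vm_membrane_sources <- function(states, motion, t, eps_mem, Lp) {
  if (length(states) == 0) return(list())
  rep_f <- repulsion_forces(states, motion, t, Lp)
  lapply(seq_along(states), function(i) {
    s <- states[[i]]
    Fel <- elastic_forces(s)
    Ftot <- Fel + rep_f[[i]]
    list(x = s$x, y = s$y, F = c(Ftot[, 1], Ftot[, 2]), eps = eps_mem)
  })
}

# one flow solve at time t: mesh, wall forces, membrane sources.  All
# membrane nodes are concatenated into a single source set so kernel
# evaluations stay few and large.
.vm_flow_state <- function(cfg, states, t) {
  mesh <- boundary_mesh(cfg$motion, cfg$n_per_wall, t,
                        eps_factor = cfg$eps_factor)
  eps_mem <- if (length(states) > 0) {
    per <- sum(sqrt(diff(c(states[[1]]$x, states[[1]]$x[1]))^2 +
                    diff(c(states[[1]]$y, states[[1]]$y[1]))^2))
    cfg$eps_factor * per / length(states[[1]]$x)
  } else {
    mesh$eps
  }
  mbs <- .vm_membrane_sources(states, cfg$motion, t, eps_mem, mesh$Lp)
  mb_all <- NULL
  if (length(mbs) > 0) {
    nn <- vapply(mbs, function(m) length(m$x), integer(1))
    Fx <- unlist(lapply(mbs, function(m) m$F[seq_len(length(m$x))]))
    Fy <- unlist(lapply(mbs, function(m) m$F[length(m$x) + seq_len(length(m$x))]))
    mb_all <- list(x = unlist(lapply(mbs, `[[`, "x")),
                   y = unlist(lapply(mbs, `[[`, "y")),
                   F = c(Fx, Fy), eps = eps_mem, sizes = nn)
  }
  A <- assemble_system(mesh)
  uw <- mesh$uw
  if (!is.null(mb_all)) {
    um <- .vm_induced_velocity(mesh$x, mesh$y, mb_all$x, mb_all$y, mb_all$F,
                               mb_all$eps, mesh$Lp, mesh$n_images,
                               mesh$gauge)
    sol <- solve_wall_forces(mesh, A, u_bc = uw, extra_velocity = um)
  } else {
    sol <- solve_wall_forces(mesh, A, u_bc = uw)
  }
  list(mesh = mesh, F = sol$F, membranes = mbs, mb_all = mb_all)
}

# node velocities of every membrane under the full superposition
.vm_membrane_velocities <- function(fs) {
  if (is.null(fs$mb_all)) return(list())
  mb <- fs$mb_all
  u <- velocity_at(mb$x, mb$y, fs$mesh, fs$F, list(mb))
  idx <- split(seq_along(mb$x), rep(seq_along(mb$sizes), mb$sizes))
  lapply(idx, function(ii) cbind(u$ux[ii], u$uy[ii]))
}

#' Run the heart-tube simulation
#'
#' @param cfg a [sim_config()].
#' @param progress print per-beat progress.
#' @return object of class `heart_sim` with the shear-stress record
#'   (`time`, `retained`, `tau_u`, `tau_l`, `normal_u`, `normal_l`), flux
#'   series (`flux`), station positions (`stations`), cell centroid tracks
#'   (`centroids`), periodic cell outline snapshots (`outlines`) and the
#'   final membrane states.
#' @export
run_heart_sim <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  motion <- cfg$motion
  Tb <- motion$T
  dt <- Tb / cfg$steps_per_beat
  n_steps <- cfg$steps_per_beat * cfg$n_beats
  sample_every <- cfg$steps_per_beat / cfg$samples_per_beat
  L <- cfg$geometry$length
  stations <- seq(0, L, length.out = cfg$n_stations + 1)[-(cfg$n_stations + 1)]

  states <- seed_membranes(cfg$membrane, motion, cfg$n_rbc,
                           region = cfg$seeding_region, seed = cfg$seed)
  areas0 <- vapply(states, function(s) abs(.vm_shoelace(s$x, s$y)), numeric(1))

  n_samp <- cfg$samples_per_beat * cfg$n_beats
  tau_u <- matrix(NA_real_, n_samp, cfg$n_stations)
  tau_l <- matrix(NA_real_, n_samp, cfg$n_stations)
  nrm_u <- matrix(NA_real_, n_samp, cfg$n_stations)
  nrm_l <- matrix(NA_real_, n_samp, cfg$n_stations)
  flux <- matrix(NA_real_, n_samp, cfg$n_stations)
  times <- numeric(n_samp)
  centroids <- array(NA_real_, c(n_samp, max(cfg$n_rbc, 1), 2))
  outlines <- vector("list", n_samp)
  isamp <- 0

  t <- 0
  for (step in seq_len(n_steps)) {
    fs <- .vm_flow_state(cfg, states, t)
    if (step %% sample_every == 1 || sample_every == 1) {
      isamp <- isamp + 1
      times[isamp] <- t
      rec <- .vm_record_sample(cfg, fs, stations)
      tau_u[isamp, ] <- rec$tau_u
      tau_l[isamp, ] <- rec$tau_l
      nrm_u[isamp, ] <- rec$nrm_u
      nrm_l[isamp, ] <- rec$nrm_l
      flux[isamp, ] <- rec$flux
      if (length(states) > 0) {
        for (i in seq_along(states)) {
          centroids[isamp, i, ] <- c(mean(states[[i]]$x), mean(states[[i]]$y))
        }
        outlines[[isamp]] <- lapply(states, function(s) cbind(s$x, s$y))
      }
    }
    if (length(states) > 0) {
      v1 <- .vm_membrane_velocities(fs)
      pred <- states
      for (i in seq_along(states)) {
        pred[[i]]$x <- states[[i]]$x + dt * v1[[i]][, 1]
        pred[[i]]$y <- states[[i]]$y + dt * v1[[i]][, 2]
      }
      fs2 <- .vm_flow_state(cfg, pred, t + dt)
      v2 <- .vm_membrane_velocities(fs2)
      for (i in seq_along(states)) {
        states[[i]]$x <- states[[i]]$x + 0.5 * dt * (v1[[i]][, 1] + v2[[i]][, 1])
        states[[i]]$y <- states[[i]]$y + 0.5 * dt * (v1[[i]][, 2] + v2[[i]][, 2])
      }
      if (any(!vapply(states, function(s) all(is.finite(s$x)) && all(is.finite(s$y)), logical(1)))) {
        stop("time-step instability (non-finite membrane positions): ",
             "reduce the time step (increase steps_per_beat)")
      }
      if (step %% cfg$reparam_every == 0) {
        states <- lapply(states, reparameterize)
      }
      .vm_check_penetration(cfg, states, t + dt)
    }
    t <- t + dt
  }

  retained <- times >= cfg$discard_beats * Tb - 1e-9
  structure(list(
    config = cfg, time = times, retained = retained,
    stations = stations,
    tau_u = tau_u, tau_l = tau_l, normal_u = nrm_u, normal_l = nrm_l,
    flux = flux, centroids = centroids, outlines = outlines,
    cells = states, cell_areas0 = areas0,
    period = Tb
  ), class = "heart_sim")
}

# shear stress + flux at the stations for one flow state
.vm_record_sample <- function(cfg, fs, stations) {
  mesh <- fs$mesh
  nw <- cfg$n_per_wall
  mbl <- if (is.null(fs$mb_all)) NULL else list(fs$mb_all)
  # station targets on each wall by periodic interpolation of the mesh
  tr <- wall_shear_stress(mesh, fs$F, membranes = mbl)
  iu <- which(tr$side == "upper")
  il <- which(tr$side == "lower")
  list(
    tau_u = .vm_pinterp(mesh$xu, tr$tau[iu], stations, mesh$Lp),
    tau_l = .vm_pinterp(mesh$xl, tr$tau[il], stations, mesh$Lp),
    nrm_u = .vm_pinterp(mesh$xu, tr$normal[iu], stations, mesh$Lp),
    nrm_l = .vm_pinterp(mesh$xl, tr$normal[il], stations, mesh$Lp),
    flux = channel_flux(mesh, fs$F, stations, membranes = mbl,
                        nq = 12)
  )
}

.vm_check_penetration <- function(cfg, states, t) {
  for (s in states) {
    yu <- wall_position(cfg$motion, s$x, t, "upper", volume_correction = TRUE)
    yl <- wall_position(cfg$motion, s$x, t, "lower", volume_correction = TRUE)
    if (any(s$y > yu) || any(s$y < yl)) {
      stop("membrane-wall penetration at t = ", signif(t, 6),
           "; state dump: cell near x = ", signif(mean(s$x), 4))
    }
  }
  invisible(TRUE)
}

#' @export
print.heart_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Heart-tube simulation: %d RBCs, %d beats (%d retained), %d stations\n",
              cfg$n_rbc, cfg$n_beats, cfg$n_beats - cfg$discard_beats,
              cfg$n_stations))
  cat(sprintf("  mean flux (retained): %.4g\n",
              mean(x$flux[x$retained, ])))
  invisible(x)
}

#' Extract the wall shear stress record
#'
#' Returns the retained-beat part of the simulation's shear-stress series in
#' the layout used by the decomposition stage.
#'
#' @param sim a `heart_sim` object.
#' @param side `"upper"` or `"lower"` wall.
#' @return object of class `wss_record`: list with `time`, `tau` (matrix
#'   samples x stations), `normal`, `stations`, `period`, `n_beats`.
#' @export
wss_record <- function(sim, side = c("upper", "lower")) {
  side <- match.arg(side)
  keep <- sim$retained
  tau <- if (side == "upper") sim$tau_u else sim$tau_l
  nrm <- if (side == "upper") sim$normal_u else sim$normal_l
  structure(list(
    time = sim$time[keep],
    tau = tau[keep, , drop = FALSE],
    normal = nrm[keep, , drop = FALSE],
    stations = sim$stations,
    period = sim$period,
    n_beats = sum(keep) / sim$config$samples_per_beat,
    side = side
  ), class = "wss_record")
}

#' Time-averaged axial concentration profile of the cells
#'
#' Mean cell-area density per axial bin (area per unit axial length),
#' averaged over retained snapshots; integrates over the tube length to the
#' total mean cell area.
#'
#' @param sim a `heart_sim` object.
#' @param bins number of axial bins.
#' @return data.frame with bin centers `x`, bin edges, and `density`.
#' @export
concentration_profile <- function(sim, bins = 40) {
  stopifnot(bins >= 1)
  L <- sim$config$geometry$length
  edges <- seq(0, L, length.out = bins + 1)
  keep <- which(sim$retained & !vapply(sim$outlines, is.null, logical(1)))
  dens <- numeric(bins)
  if (length(keep) > 0 && sim$config$n_rbc > 0) {
    for (k in keep) {
      for (poly in sim$outlines[[k]]) {
        dens <- dens + .vm_poly_bin_areas(poly[, 1], poly[, 2], edges, L)
      }
    }
    dens <- dens / length(keep)
  }
  data.frame(
    x = (edges[-1] + edges[-(bins + 1)]) / 2,
    lower = edges[-(bins + 1)], upper = edges[-1],
    density = dens / diff(edges)
  )
}

# area of a closed polygon inside each axial bin, with periodic wrapping.
# Uses the flux form area(strip) = contour integral of clamp(x)-x0 dy over a
# densely resampled polygon.
.vm_poly_bin_areas <- function(px, py, edges, L) {
  nb <- length(edges) - 1
  # shift so the polygon is contiguous around its own mean
  cx <- mean(px)
  px <- px - L * floor(cx / L)
  # dense resampling (midpoint rule on sub-segments)
  xs <- c(px, px[1])
  ys <- c(py, py[1])
  m <- 4
  xm <- c()
  dym <- c()
  t0 <- (seq_len(m) - 0.5) / m
  for (i in seq_len(length(px))) {
    xm <- c(xm, xs[i] + (xs[i + 1] - xs[i]) * t0)
    dym <- c(dym, rep((ys[i + 1] - ys[i]) / m, m))
  }
  # orientation: make counter-clockwise so areas are positive
  if (.vm_shoelace(px, py) < 0) dym <- -dym
  out <- numeric(nb)
  for (shift in c(-L, 0, L)) {
    xq <- xm + shift
    if (max(xq) < edges[1] || min(xq) > edges[nb + 1]) next
    for (b in seq_len(nb)) {
      xcl <- pmin(pmax(xq, edges[b]), edges[b + 1]) - edges[b]
      out[b] <- out[b] + sum(xcl * dym)
    }
  }
  out
}

#' Find cell-depleted axial regions
#'
#' Maximal axial intervals where the concentration falls below a fraction of
#' its spatial mean.
#'
#' @param profile output of [concentration_profile()].
#' @param threshold fraction of the spatial mean density.
#' @return data.frame with columns `start`, `end` (possibly zero rows).
#' @export
depleted_regions <- function(profile, threshold = 0.5) {
  stopifnot(nrow(profile) >= 1)
  low <- profile$density < threshold * mean(profile$density)
  runs <- rle(low)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sel <- which(runs$values)
  data.frame(
    start = profile$lower[starts[sel]],
    end = profile$upper[ends[sel]]
  )
}

#' Analytic rate of change of the channel area between two stations
#'
#' Line integral of the wall normal velocity between stations `x1 < x2`;
#' used by the flux-balance diagnostics: `flux(x2) - flux(x1)` must equal
#' its negative at every instant.
#'
#' @param motion a [wall_motion()].
#' @param x1,x2 axial stations.
#' @param t time(s).
#' @return numeric vector `d/dt area(x1, x2, t)`.
#' @export
area_rate <- function(motion, x1, x2, t) {
  xs <- seq(x1, x2, length.out = 257)
  vapply(t, function(tt) {
    vu <- wall_velocity(motion, xs, tt, "upper", volume_correction = TRUE)
    vl <- wall_velocity(motion, xs, tt, "lower", volume_correction = TRUE)
    dv <- vu - vl
    sum((dv[-1] + dv[-length(dv)]) / 2 * diff(xs))
  }, numeric(1))
}

#' Advect passive tracers in the no-cell flow
#'
#' Heun (predictor-corrector) integration of tracer trajectories in the
#' instantaneous Stokes flow of the moving walls.  Stepping from `t1` back
#' to `t0` retraces the same wall-motion sequence in reverse; by kinematic
#' reversibility of Stokes flow the tracers must return to their initial
#' positions up to integration error.
#'
#' @param motion a [wall_motion()].
#' @param x0,y0 initial tracer positions.
#' @param t0,t1 start and end times (either order).
#' @param n_steps number of time steps.
#' @param n_per_wall wall collocation points per wall.
#' @param eps_factor regularization factor for the wall mesh.
#' @return matrix with columns `x`, `y` of final tracer positions.
#' @export
advect_tracers <- function(motion, x0, y0, t0, t1, n_steps = 100,
                           n_per_wall = 64, eps_factor = 1.5) {
  stopifnot(length(x0) == length(y0))
  dt <- (t1 - t0) / n_steps
  x <- x0
  y <- y0
  solve_at <- function(t) {
    mesh <- boundary_mesh(motion, n_per_wall, t, eps_factor = eps_factor)
    list(mesh = mesh, F = solve_wall_forces(mesh)$F)
  }
  fs <- solve_at(t0)
  for (i in seq_len(n_steps)) {
    t <- t0 + (i - 1) * dt
    u1 <- velocity_at(x, y, fs$mesh, fs$F)
    fs2 <- solve_at(t + dt)
    u2 <- velocity_at(x + dt * u1$ux, y + dt * u1$uy, fs2$mesh, fs2$F)
    x <- x + 0.5 * dt * (u1$ux + u2$ux)
    y <- y + 0.5 * dt * (u1$uy + u2$uy)
    fs <- fs2
  }
  cbind(x = x, y = y)
}
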