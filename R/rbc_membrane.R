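# Elastic-shell model of a red blood cell: a closed discretized curve with
# stretching and bending resistance.  The discrete elastic energy is
#   E = (k_s/2) sum_i (|l_i|/|l0_i| - 1)^2 |l0_i|
#     + (k_b/2) sum_i theta_i^2 / ds0_i
# with l_i the edge vectors, theta_i the turning angle at node i (a discrete
# curvature kappa_i ~ theta_i / ds0_i integrated over ds0_i), and ds0_i the
# reference arc length attached to node i.  Forces are the exact negative
# gradient of E, so the force set is translation- and rotation-free to
# round-off.

#' Membrane (red blood cell) parameters
#'
#' @param k_s stretching stiffness (nondimensional, units of `mu f1 L`).
#' @param k_b bending stiffness (units of `mu f1 L^3`).
#' @param n_nodes number of nodes on the closed curve (>= 16).
#' @param semi_axes rest-shape ellipse semi-axes `c(a, b)`; the default has
#'   aspect ratio 2 and effective radius `sqrt(a b) = 0.2` chamber
#'   half-widths, i.e. half the default AVC rest half-width.
#' @param repulsion_strength near-contact repulsion force scale.
#' @param repulsion_cutoff repulsion cutoff distance (0 disables).
#' @return object of class `membrane_params`.
#' @export
membrane_params <- function(k_s = 5, k_b = 0.01, n_nodes = 32,
                            semi_axes = c(0.2 * sqrt(2), 0.2 / sqrt(2)),
                            repulsion_strength = 5,
                            repulsion_cutoff = 0.08) {
  stopifnot(k_s >= 0, k_b >= 0, n_nodes >= 16, length(semi_axes) == 2,
            all(semi_axes > 0), repulsion_cutoff >= 0)
  structure(list(
    k_s = k_s, k_b = k_b, n_nodes = as.integer(n_nodes),
    semi_axes = semi_axes,
    repulsion_strength = repulsion_strength,
    repulsion_cutoff = repulsion_cutoff
  ), class = "membrane_params")
}

#' Create a membrane at rest
#'
#' Nodes are placed on the rest ellipse at (approximately) equal arc length;
#' reference segment lengths are taken from the placed polygon, so the
#' initial state is stress-free under the stretching energy.
#'
#' @param params a [membrane_params()].
#' @param center 2-vector cell center.
#' @param angle orientation of the major axis (radians).
#' @return object of class `membrane_state` with fields `x`, `y` (node
#'   positions), `l0` (reference segment lengths), `ds0` (reference nodal arc
#'   lengths) and `area0` (initial enclosed area).
#' @export
membrane_state <- function(params, center = c(0, 0), angle = 0) {
  n <- params$n_nodes
  a <- params$semi_axes[1]
  b <- params$semi_axes[2]
  # equal-arc-length placement on the ellipse via dense resampling
  tt <- seq(0, 2 * pi, length.out = 40 * n + 1)
  ex <- a * cos(tt)
  ey <- b * sin(tt)
  s <- c(0, cumsum(sqrt(diff(ex)^2 + diff(ey)^2)))
  st <- seq(0, s[length(s)], length.out = n + 1)[-(n + 1)]
  xi <- stats::approx(s, ex, st)$y
  yi <- stats::approx(s, ey, st)$y
  ca <- cos(angle)
  sa <- sin(angle)
  x <- center[1] + ca * xi - sa * yi
  y <- center[2] + sa * xi + ca * yi
  l0 <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
  ds0 <- (l0 + c(l0[n], l0[-n])) / 2
  st_obj <- structure(list(x = x, y = y, l0 = l0, ds0 = ds0,
                           area0 = .vm_shoelace(x, y), params = params),
                      class = "membrane_state")
  st_obj
}

# signed polygon area (positive for counter-clockwise orientation)
.vm_shoelace <- function(x, y) {
  n <- length(x)
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# discrete elastic energy (used by tests and the relaxation property)
membrane_energy <- function(state) {
  p <- state$params
  n <- length(state$x)
  ex <- c(state$x[-1], state$x[1]) - state$x
  ey <- c(state$y[-1], state$y[1]) - state$y
  l <- sqrt(ex^2 + ey^2)
  Es <- 0.5 * p$k_s * sum((l / state$l0 - 1)^2 * state$l0)
  # turning angle at node i between edge i-1 and edge i
  ang <- atan2(ey, ex)
  th <- ang - c(ang[n], ang[-n])
  th <- th - 2 * pi * round(th / (2 * pi))
  Eb <- 0.5 * p$k_b * sum(th^2 / state$ds0)
  Es + Eb
}

#' Elastic membrane forces
#'
#' Exact negative gradient of the discrete stretching + bending energy with
#' respect to the node positions.
#'
#' @param state a [membrane_state()].
#' @return matrix `n x 2` of nodal forces.
#' @export
elastic_forces <- function(state) {
  p <- state$params
  x <- state$x
  y <- state$y
  n <- length(x)
  ip <- c(2:n, 1)   # i+1
  im <- c(n, 1:(n - 1)) # i-1
  ex <- x[ip] - x
  ey <- y[ip] - y
  l <- sqrt(ex^2 + ey^2)
  if (any(l == 0)) stop("geometry error: degenerate (zero-length) segment")
  # stretching: dE/d(edge i) = k_s (l_i/l0_i - 1) * ehat_i
  cs <- p$k_s * (l / state$l0 - 1)
  tx <- cs * ex / l
  ty <- cs * ey / l
  fx <- tx - tx[im]  # node i appears as tail of edge i (+) and head of i-1 (-)
  fy <- ty - ty[im]
  if (p$k_b > 0) {
    ang <- atan2(ey, ex)
    th <- ang - ang[im]
    th <- th - 2 * pi * round(th / (2 * pi))
    w <- p$k_b * th / state$ds0
    # d(angle of edge i)/d(edge i) = e_perp / l^2
    px <- -ey / l^2
    py <- ex / l^2
    # dE/d(edge i) = (w_i - w_{i+1}) * perp_i   (edge i enters theta_i with +,
    # theta_{i+1} with -)
    gx <- (w - w[ip]) * px
    gy <- (w - w[ip]) * py
    fx <- fx + (gx - gx[im])
    fy <- fy + (gy - gy[im])
  }
  # edge-to-node chain: dE/dx_i = (edge term i-1) - (edge term i), so the
  # accumulated (fx, fy) is already the negative gradient
  cbind(fx = fx, fy = fy)
}

#' Near-contact repulsion forces
#'
#' Short-range pairwise repulsion between nodes of distinct membranes and
#' between membrane nodes and the channel walls; zero beyond the cutoff,
#' equal and opposite within cell pairs.  The potential is
#' `U(d) = strength * cutoff * (1 - d/cutoff)^2 / 2` for `d < cutoff`.
#'
#' @param states list of [membrane_state()] objects.
#' @param motion optional [wall_motion()] for wall repulsion.
#' @param t time (for the instantaneous wall position).
#' @param Lp axial period used for minimum-image distances (defaults to the
#'   motion's tube length).
#' @return list of `n x 2` force matrices, one per membrane.
#' @export
repulsion_forces <- function(states, motion = NULL, t = 0, Lp = NULL) {
  if (length(states) == 0) return(list())
  p <- states[[1]]$params
  d_c <- p$repulsion_cutoff
  kr <- p$repulsion_strength
  if (is.null(Lp) && !is.null(motion)) Lp <- motion$geometry$length
  out <- lapply(states, function(s) matrix(0, length(s$x), 2))
  if (d_c <= 0) return(out)
  nm <- length(states)
  if (nm > 1) {
    for (i in seq_len(nm - 1)) {
      for (j in (i + 1):nm) {
        dx <- outer(states[[i]]$x, states[[j]]$x, "-")
        if (!is.null(Lp)) dx <- .vm_wrap(dx, Lp)
        dy <- outer(states[[i]]$y, states[[j]]$y, "-")
        # quick reject on bounding distance
        if (min(abs(dx)) > d_c || min(abs(dy)) > d_c) {
          if (min(sqrt(dx^2 + dy^2)) > d_c) next
        }
        d <- sqrt(dx^2 + dy^2)
        act <- d < d_c & d > 0
        if (!any(act)) next
        mag <- matrix(0, nrow(d), ncol(d))
        mag[act] <- kr * (1 - d[act] / d_c)
        fx <- mag * ifelse(d > 0, dx / pmax(d, 1e-12), 0)
        fy <- mag * ifelse(d > 0, dy / pmax(d, 1e-12), 0)
        out[[i]][, 1] <- out[[i]][, 1] + rowSums(fx)
        out[[i]][, 2] <- out[[i]][, 2] + rowSums(fy)
        out[[j]][, 1] <- out[[j]][, 1] - colSums(fx)
        out[[j]][, 2] <- out[[j]][, 2] - colSums(fy)
      }
    }
  }
  if (!is.null(motion)) {
    for (i in seq_len(nm)) {
      s <- states[[i]]
      yu <- wall_position(motion, s$x, t, "upper", volume_correction = TRUE)
      yl <- wall_position(motion, s$x, t, "lower", volume_correction = TRUE)
      gu <- yu - s$y
      gl <- s$y - yl
      fu <- ifelse(gu < d_c, kr * (1 - pmax(gu, 0) / d_c), 0)
      fl <- ifelse(gl < d_c, kr * (1 - pmax(gl, 0) / d_c), 0)
      out[[i]][, 2] <- out[[i]][, 2] - fu + fl
    }
  }
  out
}

#' Redistribute membrane nodes at equal arc length
#'
#' Periodic-spline resampling of the closed curve at uniform arc length,
#' followed by a uniform rescaling about the centroid that restores the
#' enclosed polygon area exactly.
#'
#' @param state a [membrane_state()].
#' @return a new `membrane_state` with uniformly spaced nodes and the same
#'   enclosed area.
#' @export
reparameterize <- function(state) {
  x <- state$x
  y <- state$y
  n <- length(x)
  if (.vm_self_intersects(x, y)) {
    stop("geometry error: membrane curve is self-intersecting")
  }
  A0 <- .vm_shoelace(x, y)
  for (pass in 1:2) {
    xc <- c(x, x[1])
    yc <- c(y, y[1])
    s <- c(0, cumsum(sqrt(diff(xc)^2 + diff(yc)^2)))
    stot <- s[n + 1]
    st <- seq(0, stot, length.out = n + 1)[-(n + 1)]
    x <- stats::spline(s, xc, xout = st, method = "periodic")$y
    y <- stats::spline(s, yc, xout = st, method = "periodic")$y
  }
  # restore enclosed area exactly by uniform scaling about the centroid
  A1 <- .vm_shoelace(x, y)
  cx <- mean(x)
  cy <- mean(y)
  sc <- sqrt(A0 / A1)
  x <- cx + sc * (x - cx)
  y <- cy + sc * (y - cy)
  out <- state
  out$x <- x
  out$y <- y
  out
}

# crude self-intersection test: any non-adjacent segment pair crossing
.vm_self_intersects <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]
    d1x <- x2[i] - x[i]; d1y <- y2[i] - y[i]
    rx <- x[js] - x[i]; ry <- y[js] - y[i]
    sx <- x2[js] - x[js]; sy <- y2[js] - y[js]
    den <- d1x * sy - d1y * sx
    ok <- abs(den) > 1e-14
    tpar <- (rx * sy - ry * sx) / ifelse(ok, den, 1)
    upar <- (rx * d1y - ry * d1x) / ifelse(ok, den, 1)
    hit <- ok & tpar > 0 & tpar < 1 & upar > 0 & upar < 1
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Seed non-overlapping membranes in a region
#'
#' Rejection-sampled placement of `n_rbc` cells with random centers and
#' orientations inside an axial interval of the tube, keeping cells clear of
#' the walls and of each other.
#'
#' @param params a [membrane_params()].
#' @param motion a [wall_motion()].
#' @param n_rbc number of cells.
#' @param region axial interval, or a matrix whose rows are intervals
#'   (sampled proportionally to length); defaults to the atrial segment.
#' @param seed RNG seed (an integer) for reproducible seeding.
#' @param t time at which wall clearance is checked.
#' @return list of [membrane_state()] objects.
#' @export
seed_membranes <- function(params, motion, n_rbc,
                           region = NULL, seed = 1, t = 0) {
  if (n_rbc == 0) return(list())
  geom <- motion$geometry
  if (is.null(region)) region <- geom$segments$atrium
  region <- matrix(region, ncol = 2)
  rmax <- max(params$semi_axes)
  rmin <- min(params$semi_axes)
  rlen <- region[, 2] - region[, 1]
  states <- list()
  old <- .vm_set_seed(seed)
  on.exit(.vm_restore_seed(old), add = TRUE)
  tries <- 0
  while (length(states) < n_rbc) {
    tries <- tries + 1
    if (tries > 2000 * n_rbc) {
      stop("seeding failed: region too crowded for ", n_rbc, " cells")
    }
    ri <- if (nrow(region) == 1) 1 else
      sample.int(nrow(region), 1, prob = rlen)
    cx <- stats::runif(1, region[ri, 1] + rmax * 0.8,
                       region[ri, 2] - rmax * 0.8)
    h <- geom$h0(cx) - motion$a(cx) # tightest wall excursion at this x
    if (h <= rmin * 1.15) next
    cy <- stats::runif(1, -(h - rmin * 1.15), h - rmin * 1.15)
    ang <- stats::runif(1, 0, pi)
    cand <- membrane_state(params, center = c(cx, cy), angle = ang)
    # wall clearance at the candidate's actual nodes (rest walls)
    yu <- wall_position(motion, cand$x, t, "upper", volume_correction = TRUE)
    yl <- wall_position(motion, cand$x, t, "lower", volume_correction = TRUE)
    marg <- 0.5 * params$repulsion_cutoff + 0.02
    if (any(cand$y > yu - marg) || any(cand$y < yl + marg)) next
    ok <- TRUE
    for (s in states) {
      dmin <- min(sqrt(outer(cand$x, s$x, "-")^2 + outer(cand$y, s$y, "-")^2))
      if (dmin < params$repulsion_cutoff * 1.2) {
        ok <- FALSE
        break
      }
    }
    if (ok) states[[length(states) + 1]] <- cand
  }
  states
}

# save/restore global RNG state around seeded sections
.vm_set_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

.vm_restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
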