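# Zero-Reynolds-number flow solver for the periodic channel, built on the
# singly periodic regularized Stokeslet kernels.  Wall force densities are
# the unknowns of a dense mobility system: the velocity they induce at the
# wall collocation points must equal the prescribed wall velocity (no-slip),
# minus any known contribution from membrane (red blood cell) forces and
# from an optional imposed mean pressure gradient.
#
# Wall traction is recovered from the stress kernels evaluated on the wall
# (which give the average of the two one-sided stresses across the force
# layer) plus half the local traction jump, which equals the local force
# density.  The reported scalar tau is the tangential traction on the wall
# exerted by the fluid, positive when it points in the +x
# (atrium-to-ventricle) direction; the normal traction is returned alongside.

# periodic linear interpolation on a uniform grid x in [0, Lp)
.vm_pinterp <- function(xg, yg, xout, Lp) {
  n <- length(xg)
  xx <- c(xg, xg[1] + Lp)
  yy <- c(yg, yg[1])
  stats::approx(xx, yy, xout %% Lp, rule = 2)$y
}

#' Build the wall collocation mesh at a time instant
#'
#' Collocation points are laid out on both walls at uniform axial spacing;
#' normals, +x tangents, arc-length quadrature weights and the prescribed
#' (no-slip) wall velocities are computed from the wall motion.  The
#' volume-conserving offset is always applied so the periodic Stokes problem
#' is solvable.
#'
#' @param motion a [wall_motion()].
#' @param n_per_wall collocation points per wall.
#' @param t time.
#' @param eps_factor regularization length in units of the collocation
#'   spacing (default 1.5).
#' @param n_images periodic images corrected to regularized form.
#' @return an object of class `boundary_mesh`.
#' @export
boundary_mesh <- function(motion, n_per_wall = 128, t = 0, eps_factor = 1.5,
                          n_images = 3) {
  stopifnot(inherits(motion, "wall_motion"), n_per_wall >= 8)
  L <- motion$geometry$length
  xg <- (seq_len(n_per_wall) - 0.5) * L / n_per_wall
  yu <- wall_position(motion, xg, t, "upper", volume_correction = TRUE)
  yl <- wall_position(motion, xg, t, "lower", volume_correction = TRUE)
  vu <- wall_velocity(motion, xg, t, "upper", volume_correction = TRUE)
  vl <- wall_velocity(motion, xg, t, "lower", volume_correction = TRUE)
  mesh <- .vm_mesh_from_walls(xg, yu, xg, yl, L, eps_factor, n_images)
  mesh$uw <- c(rep(0, 2 * n_per_wall), vu, vl)
  mesh$t <- t
  mesh$motion <- motion
  mesh
}

# internal: mesh geometry from discrete wall curves on a uniform x grid
.vm_mesh_from_walls <- function(xu, yu, xl, yl, Lp, eps_factor = 1.5,
                                n_images = 3) {
  slope <- function(y, x) {
    n <- length(x)
    dx <- Lp / n
    (y[c(2:n, 1)] - y[c(n, 1:(n - 1))]) / (2 * dx)
  }
  su <- slope(yu, xu)
  sl <- slope(yl, xl)
  nu <- length(xu)
  nl <- length(xl)
  dxu <- Lp / nu
  dxl <- Lp / nl
  # +x oriented unit tangents; outward normals point out of the fluid
  norm_u <- sqrt(1 + su^2)
  norm_l <- sqrt(1 + sl^2)
  x <- c(xu, xl)
  y <- c(yu, yl)
  tx <- c(1 / norm_u, 1 / norm_l)
  ty <- c(su / norm_u, sl / norm_l)
  nx <- c(-su / norm_u, sl / norm_l)
  ny <- c(1 / norm_u, -1 / norm_l)
  ds <- c(dxu * norm_u, dxl * norm_l)
  eps <- eps_factor * stats::median(ds)
  k <- 2 * pi / Lp
  gauge <- 1 + k * max(abs(y))
  structure(list(
    x = x, y = y, nx = nx, ny = ny, tx = tx, ty = ty, ds = ds,
    side = rep(c("upper", "lower"), c(nu, nl)),
    n = nu + nl, Lp = Lp, eps = eps, n_images = n_images, gauge = gauge,
    xu = xu, yu = yu, xl = xl, yl = yl
  ), class = "boundary_mesh")
}

#' @export
print.boundary_mesh <- function(x, ...) {
  cat(sprintf("Boundary mesh: %d collocation points, period %.3g, eps %.3g\n",
              x$n, x$Lp, x$eps))
  invisible(x)
}

#' Assemble the wall mobility operator
#'
#' Dense operator mapping wall point forces to wall-point velocities via the
#' periodic regularized Stokeslet kernel.  The operator is symmetric by
#' kernel reciprocity.
#'
#' @param mesh a [boundary_mesh()].
#' @param mu dynamic viscosity (nondimensional default 1).
#' @return a `2n x 2n` matrix (degrees of freedom ordered as all `x` force
#'   components, then all `y`).
#' @export
assemble_system <- function(mesh, mu = 1) {
  stopifnot(inherits(mesh, "boundary_mesh"))
  if (mesh$eps < min(mesh$ds) / 10) {
    warning("regularization eps < spacing/10: system may be ill-conditioned")
  }
  dx <- outer(mesh$x, mesh$x, "-")
  dy <- outer(mesh$y, mesh$y, "-")
  K <- .vm_kernel(dx, dy, mesh$eps, mesh$Lp, mesh$n_images, mesh$gauge)
  rbind(cbind(K$Sxx, K$Sxy), cbind(K$Sxy, K$Syy)) / (4 * pi * mu)
}

# background (imposed mean pressure gradient) velocity u_x(y) and its flux;
# dp/dx = -G so G > 0 drives +x flow
.vm_background_u <- function(y, G, mu = 1) -G * y^2 / (2 * mu)

#' Solve for wall force densities
#'
#' Finds wall point forces such that the total induced velocity at every
#' collocation point equals the prescribed wall velocity.  Known membrane
#' contributions enter through `extra_velocity`; an imposed mean pressure
#' gradient can be given directly (`pressure_gradient`) or determined from a
#' mean flux constraint (`mean_flux`).
#'
#' @param mesh a [boundary_mesh()].
#' @param A pre-assembled operator from [assemble_system()]; assembled on the
#'   fly when `NULL`.
#' @param u_bc prescribed wall velocities `c(ux, uy)` (defaults to the mesh's
#'   no-slip wall velocities).
#' @param extra_velocity velocity already induced at the wall points by other
#'   force systems (e.g. membranes), to be subtracted from `u_bc`.
#' @param pressure_gradient imposed mean pressure gradient `-dp/dx` (default
#'   0: pumping arises from wall motion only).
#' @param mean_flux if non-`NULL`, augment the system with the mean pressure
#'   gradient as an unknown so the flux through `flux_x` equals this value.
#' @param flux_x station for the flux constraint.
#' @param mu viscosity.
#' @return list with point forces `F` (`c(Fx, Fy)`), pressure gradient `G`,
#'   and the no-slip residual.
#' @export
solve_wall_forces <- function(mesh, A = NULL, u_bc = mesh$uw,
                              extra_velocity = NULL, pressure_gradient = 0,
                              mean_flux = NULL, flux_x = NULL, mu = 1) {
  stopifnot(inherits(mesh, "boundary_mesh"))
  if (is.null(A)) A <- assemble_system(mesh, mu)
  rhs <- u_bc
  if (!is.null(extra_velocity)) rhs <- rhs - extra_velocity
  n <- mesh$n
  if (is.null(mean_flux)) {
    G <- pressure_gradient
    rhs[seq_len(n)] <- rhs[seq_len(n)] - .vm_background_u(mesh$y, G, mu)
    F <- tryCatch(solve(A, rhs), error = function(e) {
      stop("solver error: wall mobility matrix is singular ",
           "(net translation null mode); ", conditionMessage(e))
    })
  } else {
    if (is.null(flux_x)) flux_x <- mesh$Lp / 2
    fr <- .vm_flux_row(mesh, flux_x, mu)
    # unknowns: (F, G); extra row: flux constraint, extra column: background
    # velocity of a unit pressure gradient at the wall points
    bg_col <- c(.vm_background_u(mesh$y, 1, mu), rep(0, n))
    Aaug <- rbind(cbind(A, bg_col), c(fr$row, fr$G_flux))
    rhs_aug <- c(rhs, mean_flux)
    sol <- tryCatch(solve(Aaug, rhs_aug), error = function(e) {
      stop("solver error: augmented system singular; ", conditionMessage(e))
    })
    F <- sol[seq_len(2 * n)]
    G <- unname(sol[2 * n + 1])
  }
  resid <- as.numeric(A %*% F) + .vm_background_u(mesh$y, G, mu) *
    rep(c(1, 0), each = n) - (if (is.null(extra_velocity)) u_bc else u_bc - extra_velocity)
  list(F = F, G = G, residual = max(abs(resid)))
}

# flux of the wall-force representation through station x_c: quadrature row
# over the channel cross-section, plus the flux of a unit pressure gradient
.vm_flux_row <- function(mesh, x_c, mu = 1, nq = 48) {
  ytop <- .vm_pinterp(mesh$xu, mesh$yu, x_c, mesh$Lp)
  ybot <- .vm_pinterp(mesh$xl, mesh$yl, x_c, mesh$Lp)
  gl <- .vm_gauss_legendre(nq)
  yq <- 0.5 * (ytop - ybot) * gl$nodes + 0.5 * (ytop + ybot)
  wq <- 0.5 * (ytop - ybot) * gl$weights
  dx <- outer(rep(x_c, nq), mesh$x, "-")
  dy <- outer(yq, mesh$y, "-")
  K <- .vm_kernel(dx, dy, mesh$eps, mesh$Lp, mesh$n_images, mesh$gauge)
  row <- c(crossprod(K$Sxx, wq), crossprod(K$Sxy, wq)) / (4 * pi * mu)
  G_flux <- sum(wq * .vm_background_u(yq, 1, mu))
  list(row = as.numeric(row), G_flux = G_flux, yq = yq, wq = wq)
}

# Gauss-Legendre nodes/weights on [-1, 1]
.vm_gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
}

#' Evaluate the flow velocity at arbitrary points
#'
#' Superposition of the wall force layer, any membrane force layers, and the
#' background flow of an imposed mean pressure gradient.
#'
#' @param px,py evaluation points.
#' @param mesh a [boundary_mesh()].
#' @param F wall point forces from [solve_wall_forces()].
#' @param membranes optional list of force sets, each a list with `x`, `y`,
#'   `F` (`c(Fx, Fy)`) and `eps`.
#' @param G mean pressure gradient.
#' @param mu viscosity.
#' @return list with components `ux`, `uy`.
#' @export
velocity_at <- function(px, py, mesh, F, membranes = NULL, G = 0, mu = 1) {
  u <- .vm_induced_velocity(px, py, mesh$x, mesh$y, F, mesh$eps, mesh$Lp,
                            mesh$n_images, mesh$gauge, mu)
  np <- length(px)
  ux <- u[seq_len(np)]
  uy <- u[np + seq_len(np)]
  for (mb in membranes) {
    um <- .vm_induced_velocity(px, py, mb$x, mb$y, mb$F, mb$eps, mesh$Lp,
                               mesh$n_images, mesh$gauge, mu)
    ux <- ux + um[seq_len(np)]
    uy <- uy + um[np + seq_len(np)]
  }
  ux <- ux + .vm_background_u(py, G, mu)
  list(ux = ux, uy = uy)
}

#' Wall traction and shear stress
#'
#' Computes the fluid traction vector at every wall collocation point and
#' returns its tangential component `tau` (sign convention: positive when
#' the traction on the wall points in the +x, atrium-to-ventricle direction)
#' and its normal component.
#'
#' @inheritParams velocity_at
#' @return data frame with `x`, `y`, `side`, `tau`, `normal`.
#' @export
wall_shear_stress <- function(mesh, F, membranes = NULL, G = 0, mu = 1) {
  tr <- .vm_induced_traction(mesh$x, mesh$y, mesh$nx, mesh$ny,
                             mesh$x, mesh$y, F, mesh$eps, mesh$Lp,
                             mesh$n_images, mu)
  n <- mesh$n
  tvx <- tr[seq_len(n)]
  tvy <- tr[n + seq_len(n)]
  for (mb in membranes) {
    trm <- .vm_induced_traction(mesh$x, mesh$y, mesh$nx, mesh$ny,
                                mb$x, mb$y, mb$F, mb$eps, mesh$Lp,
                                mesh$n_images, mu)
    tvx <- tvx + trm[seq_len(n)]
    tvy <- tvy + trm[n + seq_len(n)]
  }
  # half the local traction jump across the wall force layer: the density
  # f = F/ds is the full jump; the kernel evaluation on the layer gives the
  # two-sided average, and the fluid (interior) side adds +f/2
  fdx <- F[seq_len(n)] / mesh$ds
  fdy <- F[n + seq_len(n)] / mesh$ds
  tvx <- tvx + 0.5 * fdx
  tvy <- tvy + 0.5 * fdy
  # background stress of the imposed mean pressure gradient (p = -G x)
  if (G != 0) {
    sxy <- -G * mesh$y
    sp <- G * mesh$x
    tvx <- tvx + sp * mesh$nx + sxy * mesh$ny
    tvy <- tvy + sxy * mesh$nx + sp * mesh$ny
  }
  # (tvx, tvy) is sigma . n with n outward from the fluid, i.e. the traction
  # exerted on the fluid; the traction exerted by the fluid on the wall is
  # its negative.  Positive `normal` means the fluid pushes on the wall.
  data.frame(
    x = mesh$x, y = mesh$y, side = mesh$side,
    tau = -(tvx * mesh$tx + tvy * mesh$ty),
    normal = -(tvx * mesh$nx + tvy * mesh$ny)
  )
}

#' Instantaneous flux through a cross-section
#'
#' Gauss-Legendre quadrature of the axial velocity across the channel at
#' station `x_c`.
#'
#' @inheritParams velocity_at
#' @param x_c axial station(s).
#' @return numeric vector of fluxes.
#' @export
channel_flux <- function(mesh, F, x_c, membranes = NULL, G = 0, mu = 1,
                         nq = 48) {
  ns <- length(x_c)
  ytop <- .vm_pinterp(mesh$xu, mesh$yu, x_c, mesh$Lp)
  ybot <- .vm_pinterp(mesh$xl, mesh$yl, x_c, mesh$Lp)
  gl <- .vm_gauss_legendre(nq)
  # all stations x all quadrature nodes in one kernel evaluation
  yq <- outer(0.5 * (ytop - ybot), gl$nodes) + 0.5 * (ytop + ybot)
  wq <- outer(0.5 * (ytop - ybot), gl$weights)
  xq <- matrix(x_c, ns, nq)
  u <- velocity_at(c(xq), c(yq), mesh, F, membranes, G, mu)
  rowSums(matrix(u$ux * c(wq), ns, nq))
}
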