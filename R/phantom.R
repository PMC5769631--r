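# Synthetic two-channel heart-tube image phantoms with known ground truth.
# A curved tube with an elliptic cross-section carries a green intensity
# shell along its whole length; two "photoconverted" red bands flank an
# unlabeled gap whose arc length is prescribed per timepoint.  The gap
# ground truth (and its optional azimuthal modulation) is what the
# unfolding pipeline must recover.

#' Specify a heart-tube image phantom
#'
#' All geometry is in physical units (microns).  Band edges are defined on
#' centerline arc length and swept around the full azimuth (rings); an
#' optional sinusoidal per-azimuth edge offset modulates the gap so
#' azimuth-resolved length recovery can be tested.
#'
#' @param centerline matrix of ordered 3D control points (microns); the
#'   default is a gently curved tube along x.
#' @param semi_axes cross-section semi-axes `c(a, b)` in microns, in the
#'   directions of the two transported normals.
#' @param shell_thickness intensity shell thickness (microns); must be
#'   smaller than the minor semi-axis.
#' @param spacing voxel spacing (microns per voxel, per axis).
#' @param gap1,gap2 unlabeled gap arc length (microns) at timepoints 1, 2.
#' @param band_length arc length of each labeled band.
#' @param gap_offset_amplitude amplitude (microns) of the sinusoidal
#'   per-azimuth gap modulation (split equally between the two inner edges).
#' @param gap_offset_phase phase of the modulation (radians).
#' @param bg,fg background and foreground intensity levels.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed RNG seed for the noise field.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(centerline = NULL,
                         semi_axes = c(12, 9),
                         shell_thickness = 3,
                         spacing = c(1.5, 1.5, 1.5),
                         gap1 = 40, gap2 = 28,
                         band_length = 25,
                         gap_offset_amplitude = 0,
                         gap_offset_phase = 0,
                         bg = 10, fg = 200, noise_sd = 5,
                         seed = 1) {
  if (is.null(centerline)) {
    xs <- seq(0, 150, length.out = 7)
    centerline <- cbind(xs, 12 * sin(pi * xs / 150), rep(0, 7))
  }
  stopifnot(is.matrix(centerline), ncol(centerline) == 3,
            nrow(centerline) >= 3,
            all(spacing > 0), all(semi_axes > 0),
            shell_thickness > 0, shell_thickness < min(semi_axes),
            gap1 > 0, gap2 > 0, band_length > 0)
  cv <- .vm_resample_curve(centerline, n_dense = 512)
  stot <- cv$s[length(cv$s)]
  need <- max(gap1, gap2) + 2 * band_length
  if (need >= stot * 0.9) {
    stop("spec error: bands + gap do not fit inside the tube arc length")
  }
  structure(list(
    centerline = centerline, semi_axes = semi_axes,
    shell_thickness = shell_thickness, spacing = spacing,
    gap = c(gap1, gap2), band_length = band_length,
    gap_offset_amplitude = gap_offset_amplitude,
    gap_offset_phase = gap_offset_phase,
    bg = bg, fg = fg, noise_sd = noise_sd, seed = as.integer(seed),
    arc_length = stot
  ), class = "phantom_spec")
}

#' Generate a two-channel 3D phantom stack
#'
#' @param spec a [phantom_spec()].
#' @param timepoint 1 or 2 (selects the gap length).
#' @return object of class `phantom`: list with 3D arrays `green`, `red`,
#'   voxel `spacing`, physical `origin`, and a `ground_truth` list carrying
#'   the exact gap arc length, band edge positions, and the azimuthal gap
#'   modulation.
#' @export
make_phantom <- function(spec, timepoint = 1) {
  stopifnot(inherits(spec, "phantom_spec"), timepoint %in% c(1, 2))
  gap <- spec$gap[timepoint]
  cv <- .vm_resample_curve(spec$centerline,
                           n_dense = max(256, ceiling(spec$arc_length /
                                                        (0.4 * min(spec$spacing)))))
  fr <- .vm_rmf(cv$points, cv$tangent)
  a <- spec$semi_axes[1]
  b <- spec$semi_axes[2]
  r_out <- max(a, b) + spec$shell_thickness
  margin <- r_out + 4 * max(spec$spacing)
  origin <- apply(cv$points, 2, min) - margin
  extent <- apply(cv$points, 2, max) + margin - origin
  dims <- ceiling(extent / spec$spacing) + 1
  if (prod(dims) > 3e7) {
    stop("sizing error: tube would need more than 3e7 voxels; coarsen ",
         "spacing or shrink the centerline")
  }
  # band edges on arc length, centered on the tube
  smid <- spec$arc_length / 2
  e1 <- smid - gap / 2 # ventricular edge of the atrial-side band
  e2 <- smid + gap / 2 # atrial edge of the ventricular-side band
  b1 <- c(e1 - spec$band_length, e1)
  b2 <- c(e2, e2 + spec$band_length)
  if (b1[1] < 0 || b2[2] > spec$arc_length) {
    stop("spec error: bands fall outside the tube arc-length range")
  }

  green <- array(0, dims)
  red <- array(0, dims)
  # voxel center coordinates per axis (physical, 0-based index * spacing)
  gx <- origin[1] + (seq_len(dims[1]) - 1) * spec$spacing[1]
  gy <- origin[2] + (seq_len(dims[2]) - 1) * spec$spacing[2]
  gz <- origin[3] + (seq_len(dims[3]) - 1) * spec$spacing[3]
  cx <- cv$points[, 1]
  nyz <- dims[2] * dims[3]
  yz_y <- rep(gy, times = dims[3])
  yz_z <- rep(gz, each = dims[2])
  half <- spec$shell_thickness / 2
  damp <- spec$gap_offset_amplitude
  dphs <- spec$gap_offset_phase
  for (ix in seq_len(dims[1])) {
    vx <- gx[ix]
    cand <- which(abs(cx - vx) <= r_out + half + 2 * max(spec$spacing))
    if (length(cand) == 0) next
    # nearest centerline sample per in-slab voxel
    dx2 <- (vx - cx[cand])^2
    d2 <- outer(rep(1, nyz), dx2) +
      outer(yz_y, cv$points[cand, 2], function(p, q) (p - q)^2) +
      outer(yz_z, cv$points[cand, 3], function(p, q) (p - q)^2)
    jmin <- max.col(-d2, ties.method = "first")
    near <- cand[jmin]
    dmin2 <- d2[cbind(seq_len(nyz), jmin)]
    sel <- dmin2 <= (r_out + half + max(spec$spacing))^2
    if (!any(sel)) next
    vsel <- which(sel)
    ns <- near[sel]
    dvx <- vx - cv$points[ns, 1]
    dvy <- yz_y[vsel] - cv$points[ns, 2]
    dvz <- yz_z[vsel] - cv$points[ns, 3]
    u <- dvx * fr$n1[ns, 1] + dvy * fr$n1[ns, 2] + dvz * fr$n1[ns, 3]
    v <- dvx * fr$n2[ns, 1] + dvy * fr$n2[ns, 2] + dvz * fr$n2[ns, 3]
    theta <- atan2(v, u)
    rad <- sqrt(u^2 + v^2)
    r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    inshell <- abs(rad - r_ell) <= half
    if (!any(inshell)) next
    svox <- cv$s[ns]
    off <- 0.5 * damp * sin(theta + dphs)
    inband <- (svox >= b1[1] & svox <= b1[2] - off) |
      (svox >= b2[1] + off & svox <= b2[2])
    # array layout [i, j, k] with i fastest: linear = i + (jk - 1) * nx
    lin <- ix + (vsel[inshell] - 1) * dims[1]
    green[lin] <- spec$fg
    linr <- ix + (vsel[inshell & inband] - 1) * dims[1]
    red[linr] <- spec$fg
  }
  green <- .vm_gauss_smooth3(green, 1)
  red <- .vm_gauss_smooth3(red, 1)
  old <- .vm_set_seed(spec$seed + timepoint)
  on.exit(.vm_restore_seed(old), add = TRUE)
  if (spec$noise_sd > 0) {
    green <- green + stats::rnorm(length(green), 0, spec$noise_sd)
    red <- red + stats::rnorm(length(red), 0, spec$noise_sd)
  }
  green <- pmax(green + spec$bg, 0)
  red <- pmax(red + spec$bg, 0)
  dim(green) <- dims
  dim(red) <- dims
  structure(list(
    green = green, red = red,
    spacing = spec$spacing, origin = origin,
    ground_truth = list(
      timepoint = timepoint, gap_length_um = gap,
      band1 = b1, band2 = b2,
      gap_offset_amplitude = damp, gap_offset_phase = dphs,
      arc_length = spec$arc_length,
      centerline = cv, frames = fr
    )
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom stack %s, spacing (%s) um, gap %.4g um (timepoint %d)\n",
              paste(dim(x$green), collapse = "x"),
              paste(x$spacing, collapse = ", "),
              x$ground_truth$gap_length_um, x$ground_truth$timepoint))
  invisible(x)
}

#' Write a phantom as a two-channel multi-page TIFF plus ground truth
#'
#' Pages are ordered (channel, z): all green z-planes, then all red
#' z-planes, as 32-bit float TIFF.  A JSON sidecar stores voxel spacing,
#' origin and channel layout; a CSV sidecar stores the ground truth.
#'
#' @param phantom a [make_phantom()] result.
#' @param path output TIFF path; sidecars get `.json` / `_truth.csv`
#'   suffixes.
#' @return invisibly, the paths written.
#' @export
write_phantom_tiff <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom"))
  d <- dim(phantom$green)
  sc <- max(phantom$green, phantom$red)
  pages <- c(
    lapply(seq_len(d[3]), function(k) t(phantom$green[, , k]) / sc),
    lapply(seq_len(d[3]), function(k) t(phantom$red[, , k]) / sc)
  )
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(spacing = phantom$spacing, origin = phantom$origin,
               dims = d, n_channels = 2, intensity_scale = sc,
               page_order = "channel-major (all green z, then all red z)")
  jpath <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(meta, jpath, auto_unbox = TRUE, digits = NA)
  gt <- phantom$ground_truth
  cpath <- paste0(tools::file_path_sans_ext(path), "_truth.csv")
  utils::write.csv(data.frame(
    timepoint = gt$timepoint, gap_length_um = gt$gap_length_um,
    band1_start = gt$band1[1], band1_end = gt$band1[2],
    band2_start = gt$band2[1], band2_end = gt$band2[2],
    gap_offset_amplitude = gt$gap_offset_amplitude,
    gap_offset_phase = gt$gap_offset_phase
  ), cpath, row.names = FALSE)
  invisible(c(tiff = path, json = jpath, truth = cpath))
}

#' Read a phantom written by [write_phantom_tiff()]
#'
#' @param path TIFF path (the JSON sidecar must sit alongside).
#' @return list with `green`, `red`, `spacing`, `origin`.
#' @export
read_phantom_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dims)
  nz <- d[3]
  toarr <- function(pp) {
    out <- array(0, d)
    for (k in seq_len(nz)) out[, , k] <- t(pp[[k]])
    out * meta$intensity_scale
  }
  list(green = toarr(pages[seq_len(nz)]),
       red = toarr(pages[nz + seq_len(nz)]),
       spacing = meta$spacing, origin = meta$origin)
}
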