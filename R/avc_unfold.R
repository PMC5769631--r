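# Quantification of tissue convergence from two-timepoint, two-channel 3D
# stacks: fit a parametric tube axis through user seed points, project the
# shell intensity onto a cylindrical (arc length x azimuth) parameterization,
# unfold to 2D, locate the photoconverted band edges per azimuth, and
# compute per-azimuth and per-quadrant shortening factors of the unlabeled
# gap.

#' Fit a tube centerline through seed points
#'
#' Each seed point is refined by iterated intensity-weighted centroiding in
#' a local ball (the centroid of a shell ring lies on the tube axis), then a
#' smooth curve is fitted through the refined points and resampled densely
#' with an arc-length parameterization and rotation-minimizing frames.
#'
#' @param img 3D intensity array (the structural/green channel).
#' @param spacing voxel spacing (microns per voxel, per axis).
#' @param seeds matrix of >= 3 ordered seed points (physical units,
#'   atrium to ventricle), inside the lumen.
#' @param origin physical position of voxel (0,0,0).
#' @param refine_radius centroiding ball radius (microns).
#' @param iterations centroid refinement passes.
#' @return object of class `tube_centerline`: dense `points`, arc length
#'   `s`, `tangent`, frames `n1`, `n2`, refined control points.
#' @export
fit_centerline <- function(img, spacing, seeds, origin = c(0, 0, 0),
                           refine_radius = 18, iterations = 3) {
  stopifnot(is.array(img), length(dim(img)) == 3)
  seeds <- as.matrix(seeds)
  if (nrow(seeds) < 3) {
    stop("argument error: at least 3 seed points are required")
  }
  d <- dim(img)
  upper <- origin + (d - 1) * spacing
  if (any(t(seeds) < origin) || any(t(seeds) > upper)) {
    stop("argument error: seed points outside the image volume")
  }
  bglevel <- stats::quantile(img, 0.5)
  ctrl <- seeds
  for (it in seq_len(iterations)) {
    for (i in seq_len(nrow(ctrl))) {
      p <- ctrl[i, ]
      lo <- pmax(floor((p - refine_radius - origin) / spacing), 0)
      hi <- pmin(ceiling((p + refine_radius - origin) / spacing), d - 1)
      ii <- lo[1]:hi[1]
      jj <- lo[2]:hi[2]
      kk <- lo[3]:hi[3]
      sub <- img[ii + 1, jj + 1, kk + 1, drop = FALSE]
      px <- origin[1] + ii * spacing[1]
      py <- origin[2] + jj * spacing[2]
      pz <- origin[3] + kk * spacing[3]
      W <- pmax(sub - bglevel, 0)
      # restrict to the ball
      DX <- outer(outer((px - p[1])^2, (py - p[2])^2, "+"), (pz - p[3])^2, "+")
      W[DX > refine_radius^2] <- 0
      tw <- sum(W)
      if (tw <= 0) next
      ctrl[i, ] <- c(
        sum(W * array(rep(px, times = length(py) * length(pz)), dim(W))),
        sum(W * array(rep(rep(py, each = length(px)), times = length(pz)), dim(W))),
        sum(W * array(rep(pz, each = length(px) * length(py)), dim(W)))
      ) / tw
    }
  }
  cv <- .vm_resample_curve(ctrl, n_dense = 512, smooth = nrow(ctrl) >= 8)
  fr <- .vm_rmf(cv$points, cv$tangent)
  structure(list(
    points = cv$points, s = cv$s, tangent = cv$tangent,
    n1 = fr$n1, n2 = fr$n2, controls = ctrl
  ), class = "tube_centerline")
}

#' @export
print.tube_centerline <- function(x, ...) {
  cat(sprintf("Tube centerline: arc length %.4g um, %d samples\n",
              max(x$s), nrow(x$points)))
  invisible(x)
}

#' Unfold a tube stack to an (arc length x azimuth) image
#'
#' For each arc-length/azimuth pair a radial ray is cast from the centerline
#' in the frame direction; the shell radius is located at the (sub-sample,
#' parabolically refined) peak of the structural-channel profile and the
#' projected intensity of each channel is the maximum within a radial band
#' around that radius.  Azimuth `theta = 0` is anchored to the projection of
#' `ref_dir` onto each cross-section.
#'
#' @param channels list with 3D arrays `green` and `red`.
#' @param spacing,origin voxel geometry.
#' @param centerline a [fit_centerline()] result.
#' @param n_s,n_theta output grid (rows = arc length, cols = azimuth).
#' @param r_max maximal ray radius (microns).
#' @param band_halfwidth radial half-width of the projection band (microns).
#' @param ref_dir anatomical reference direction for `theta = 0`.
#' @param s_range optional arc-length window `c(s0, s1)` to unfold.
#' @return object of class `unfolded_image`: matrices `green`, `red`,
#'   `radius` (`n_s x n_tot`), grids `s`, `theta` (degrees), and the
#'   missing-pixel mask.
#' @export
unfold <- function(channels, spacing, centerline, origin = c(0, 0, 0),
                   n_s = 96, n_theta = 64, r_max = 30,
                   band_halfwidth = 3, ref_dir = c(0, 0, 1),
                   s_range = NULL) {
  stopifnot(n_theta >= 8, inherits(centerline, "tube_centerline"))
  if (is.null(s_range)) s_range <- range(centerline$s)
  sgrid <- seq(s_range[1], s_range[2], length.out = n_s)
  thg <- (seq_len(n_theta) - 1) / n_theta * 2 * pi
  # interpolate centerline quantities onto the s grid
  interp_cols <- function(M) {
    apply(M, 2, function(col) stats::approx(centerline$s, col, sgrid,
                                            rule = 2)$y)
  }
  P <- interp_cols(centerline$points)
  Tg <- interp_cols(centerline$tangent)
  Tg <- Tg / sqrt(rowSums(Tg^2))
  N1 <- interp_cols(centerline$n1)
  N1 <- N1 - Tg * rowSums(N1 * Tg)
  N1 <- N1 / sqrt(rowSums(N1^2))
  N2 <- cbind(
    Tg[, 2] * N1[, 3] - Tg[, 3] * N1[, 2],
    Tg[, 3] * N1[, 1] - Tg[, 1] * N1[, 3],
    Tg[, 1] * N1[, 2] - Tg[, 2] * N1[, 1]
  )
  # rotate frames so theta = 0 points along the projected reference
  refm <- matrix(ref_dir, n_s, 3, byrow = TRUE)
  refp <- refm - Tg * rowSums(refm * Tg)
  nrm <- sqrt(rowSums(refp^2))
  ok <- nrm > 1e-8
  alpha <- numeric(n_s)
  alpha[ok] <- atan2(rowSums(refp * N2)[ok], rowSums(refp * N1)[ok])
  M1 <- N1 * cos(alpha) + N2 * sin(alpha)
  M2 <- -N1 * sin(alpha) + N2 * cos(alpha)

  dr <- 0.5 * min(spacing)
  rg <- seq(dr, r_max, by = dr)
  nr <- length(rg)
  # sample positions: [n_s, n_theta, nr]
  dirx <- outer(M1[, 1], cos(thg)) + outer(M2[, 1], sin(thg))
  diry <- outer(M1[, 2], cos(thg)) + outer(M2[, 2], sin(thg))
  dirz <- outer(M1[, 3], cos(thg)) + outer(M2[, 3], sin(thg))
  px <- outer(c(dirx), rg) + P[, 1]
  py <- outer(c(diry), rg) + P[, 2]
  pz <- outer(c(dirz), rg) + P[, 3]
  gi <- .vm_trilinear(channels$green, (px - origin[1]) / spacing[1],
                      (py - origin[2]) / spacing[2],
                      (pz - origin[3]) / spacing[3])
  ri <- .vm_trilinear(channels$red, (px - origin[1]) / spacing[1],
                      (py - origin[2]) / spacing[2],
                      (pz - origin[3]) / spacing[3])
  dim(gi) <- c(n_s * n_theta, nr)
  dim(ri) <- c(n_s * n_theta, nr)
  # shell radius: peak of the green radial profile, parabolic refinement
  pk <- max.col(replace(gi, is.na(gi), -Inf), ties.method = "first")
  npix <- n_s * n_theta
  radius <- rep(NA_real_, npix)
  gout <- rep(NA_real_, npix)
  rout <- rep(NA_real_, npix)
  valid <- is.finite(gi[cbind(seq_len(npix), pk)]) & pk > 1 & pk < nr
  # a ray whose profile never rose above background is also missing
  peakval <- gi[cbind(seq_len(npix), pk)]
  floorval <- apply(gi, 1, function(v) stats::median(v, na.rm = TRUE))
  valid <- valid & (peakval > floorval + 1e-6)
  iv <- which(valid)
  y1 <- gi[cbind(iv, pk[iv] - 1)]
  y2 <- gi[cbind(iv, pk[iv])]
  y3 <- gi[cbind(iv, pk[iv] + 1)]
  den <- y1 - 2 * y2 + y3
  delta <- ifelse(is.finite(den) & abs(den) > 1e-12,
                  0.5 * (y1 - y3) / den, 0)
  delta[!is.finite(delta)] <- 0
  delta <- pmin(pmax(delta, -0.5), 0.5)
  radius[iv] <- rg[pk[iv]] + delta * dr
  # projected intensity: max within the radial band around the shell
  bw <- max(1L, round(band_halfwidth / dr))
  for (q in iv) {
    win <- max(1, pk[q] - bw):min(nr, pk[q] + bw)
    gout[q] <- max(gi[q, win], na.rm = TRUE)
    rout[q] <- max(ri[q, win], na.rm = TRUE)
  }
  shape <- function(v) matrix(v, n_s, n_theta)
  structure(list(
    green = shape(gout), red = shape(rout), radius = shape(radius),
    s = sgrid, theta = thg * 180 / pi,
    missing = shape(!valid),
    ds = diff(sgrid[1:2]), dtheta = 360 / n_theta
  ), class = "unfolded_image")
}

#' @export
print.unfolded_image <- function(x, ...) {
  cat(sprintf("Unfolded image: %d arc-length x %d azimuth samples, %.3g%% missing\n",
              length(x$s), length(x$theta), 100 * mean(x$missing)))
  invisible(x)
}

#' Per-azimuth length of the unlabeled gap
#'
#' For each azimuth column the red-channel profile along arc length is
#' smoothed, binarized at a half-maximum threshold, and the arc-length
#' distance between the atrial-side band's ventricular edge and the
#' ventricular-side band's atrial edge is returned with sub-sample (linear)
#' edge interpolation.  Columns with fewer than two detected bands yield
#' `NA`.
#'
#' @param uf an [unfold()] result.
#' @param threshold_frac edge threshold as a fraction of the column's band
#'   plateau.
#' @param min_run minimal band width in samples.
#' @param target `"gap"` (default) measures the unlabeled gap between the
#'   two photoconverted bands; `"band"` measures the summed arc length of
#'   the photoconverted bands themselves.
#' @return numeric vector of lengths `L(theta)` (microns), with the
#'   azimuth grid as names attribute `theta`.
#' @export
measure_L <- function(uf, threshold_frac = 0.5, min_run = 3,
                      target = c("gap", "band")) {
  stopifnot(inherits(uf, "unfolded_image"))
  target <- match.arg(target)
  nth <- length(uf$theta)
  L <- rep(NA_real_, nth)
  n_missing_cols <- 0
  for (j in seq_len(nth)) {
    prof <- uf$red[, j]
    bad <- !is.finite(prof)
    if (mean(bad) > 0.3) {
      n_missing_cols <- n_missing_cols + 1
      next
    }
    prof[bad] <- min(prof[!bad])
    prof <- stats::filter(prof, rep(1 / 3, 3), circular = FALSE)
    prof[is.na(prof)] <- min(prof, na.rm = TRUE)
    prof <- as.numeric(prof)
    # plateau level: high quantile of the profile (robust to noise spikes)
    plateau <- stats::quantile(prof, 0.9)
    base <- stats::quantile(prof, 0.1)
    if (plateau - base <= 0) next
    thr <- base + threshold_frac * (plateau - base)
    above <- prof >= thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    bands <- which(r$values & r$lengths >= min_run)
    if (target == "band") {
      if (length(bands) == 0) {
        n_missing_cols <- n_missing_cols + 1
        next
      }
      L[j] <- sum(uf$s[ends[bands]] - uf$s[starts[bands]] + uf$ds)
      next
    }
    if (length(bands) < 2) {
      if (length(bands) == 1 &&
          r$lengths[bands] >= length(prof) - 2 * min_run) {
        L[j] <- 0 # fully photoconverted column: no gap
      }
      n_missing_cols <- n_missing_cols + 1
      next
    }
    b1 <- bands[1]
    b2 <- bands[length(bands)]
    # falling edge of band 1 (sub-sample)
    i1 <- ends[b1]
    e1 <- if (i1 < length(prof)) {
      uf$s[i1] + (prof[i1] - thr) / (prof[i1] - prof[i1 + 1]) * uf$ds
    } else {
      uf$s[i1]
    }
    # rising edge of band 2
    i2 <- starts[b2]
    e2 <- if (i2 > 1) {
      uf$s[i2] - (prof[i2] - thr) / (prof[i2] - prof[i2 - 1]) * uf$ds
    } else {
      uf$s[i2]
    }
    L[j] <- max(e2 - e1, 0)
  }
  if (n_missing_cols > 0) {
    message(n_missing_cols, " azimuth column(s) without two detectable bands")
  }
  attr(L, "theta") <- uf$theta
  L
}

#' Shortening factors per azimuth and per quadrant
#'
#' `shortening = (L2 - L1)/L1` per azimuth (negative = tissue convergence),
#' averaged over four contiguous 90-degree quadrants centered at
#' `offset + (0, 90, 180, 270)` degrees and labeled `a` (superior),
#' `b` (exterior), `c` (inferior), `d` (interior).
#'
#' @param L1,L2 per-azimuth gap lengths at timepoints 1 and 2 (same grid).
#' @param quadrant_offset angular offset (degrees) mapping image azimuth to
#'   the anatomical quadrant frame.
#' @return object of class `shortening_result`: per-azimuth table and
#'   per-quadrant `mean`, `sd`, `n`; quadrants with no valid azimuth are
#'   flagged `NA`.
#' @export
shortening <- function(L1, L2, quadrant_offset = 0) {
  th <- attr(L1, "theta")
  if (is.null(th)) th <- seq(0, 360, length.out = length(L1) + 1)[-(length(L1) + 1)]
  stopifnot(length(L1) == length(L2))
  valid <- is.finite(L1) & is.finite(L2) & L1 > 0
  sh <- rep(NA_real_, length(L1))
  sh[valid] <- (L2[valid] - L1[valid]) / L1[valid]
  centers <- (quadrant_offset + c(0, 90, 180, 270)) %% 360
  labels <- c("a", "b", "c", "d")
  dang <- function(x, c0) {
    d <- (x - c0) %% 360
    pmin(d, 360 - d)
  }
  qd <- character(length(th))
  for (i in seq_along(th)) {
    qd[i] <- labels[which.min(dang(th[i], centers))]
  }
  qtab <- do.call(rbind, lapply(labels, function(l) {
    v <- sh[qd == l & valid]
    data.frame(quadrant = l,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v))
  }))
  structure(list(
    theta = th, L1 = L1, L2 = L2, shortening = sh, quadrant = qd,
    quadrants = qtab, offset = quadrant_offset
  ), class = "shortening_result")
}

#' @export
print.shortening_result <- function(x, ...) {
  cat("Shortening factors (L2 - L1)/L1 by quadrant:\n")
  print(x$quadrants, row.names = FALSE)
  invisible(x)
}
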