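# Shared geometry and image utilities: centerline resampling,
# rotation-minimizing frames, trilinear interpolation, separable Gaussian
# smoothing of 3D stacks.

# Fit a smooth curve through ordered 3D control points and resample densely.
# Returns points, cumulative arc length and unit tangents.
.vm_resample_curve <- function(ctrl, n_dense = 400, smooth = FALSE) {
  stopifnot(is.matrix(ctrl), ncol(ctrl) == 3, nrow(ctrl) >= 3)
  # chord-length parameterization
  d <- sqrt(rowSums((ctrl[-1, , drop = FALSE] -
                     ctrl[-nrow(ctrl), , drop = FALSE])^2))
  u <- c(0, cumsum(d))
  uu <- seq(0, u[length(u)], length.out = n_dense)
  fit1 <- function(y) {
    if (smooth && length(u) >= 8) {
      stats::predict(stats::smooth.spline(u, y, df = min(length(u) - 1, 6)),
                     uu)$y
    } else {
      stats::spline(u, y, xout = uu)$y
    }
  }
  P <- cbind(fit1(ctrl[, 1]), fit1(ctrl[, 2]), fit1(ctrl[, 3]))
  seg <- sqrt(rowSums((P[-1, ] - P[-n_dense, ])^2))
  s <- c(0, cumsum(seg))
  # unit tangents by central differences
  tg <- rbind(P[2, ] - P[1, ], P[-(1:2), ] - P[1:(n_dense - 2), ],
              P[n_dense, ] - P[n_dense - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = P, s = s, tangent = tg)
}

# Rotation-minimizing frames along a sampled curve (double reflection
# method).  Returns n1, n2 with (tangent, n1, n2) right-handed.
.vm_rmf <- function(points, tangent) {
  n <- nrow(points)
  n1 <- matrix(0, n, 3)
  # initial normal: any direction orthogonal to t[1]
  t1 <- tangent[1, ]
  ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  v <- ref - sum(ref * t1) * t1
  n1[1, ] <- v / sqrt(sum(v^2))
  for (i in seq_len(n - 1)) {
    v1 <- points[i + 1, ] - points[i, ]
    c1 <- sum(v1 * v1)
    rL <- n1[i, ] - (2 / c1) * sum(v1 * n1[i, ]) * v1
    tL <- tangent[i, ] - (2 / c1) * sum(v1 * tangent[i, ]) * v1
    v2 <- tangent[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    n1[i + 1, ] <- if (c2 > 1e-14) rL - (2 / c2) * sum(v2 * rL) * v2 else rL
  }
  n2 <- cbind(
    tangent[, 2] * n1[, 3] - tangent[, 3] * n1[, 2],
    tangent[, 3] * n1[, 1] - tangent[, 1] * n1[, 3],
    tangent[, 1] * n1[, 2] - tangent[, 2] * n1[, 1]
  )
  list(n1 = n1, n2 = n2)
}

# Trilinear interpolation of a 3D array at fractional 0-based voxel
# coordinates; NA outside the array.
.vm_trilinear <- function(arr, ci, cj, ck) {
  d <- dim(arr)
  out <- rep(NA_real_, length(ci))
  ok <- ci >= 0 & ci <= d[1] - 1 & cj >= 0 & cj <= d[2] - 1 &
    ck >= 0 & ck <= d[3] - 1
  if (!any(ok)) return(out)
  ci <- ci[ok]; cj <- cj[ok]; ck <- ck[ok]
  i0 <- pmin(floor(ci), d[1] - 2); fi <- ci - i0
  j0 <- pmin(floor(cj), d[2] - 2); fj <- cj - j0
  k0 <- pmin(floor(ck), d[3] - 2); fk <- ck - k0
  idx <- function(i, j, k) arr[cbind(i + 1, j + 1, k + 1)]
  v <- idx(i0, j0, k0) * (1 - fi) * (1 - fj) * (1 - fk) +
    idx(i0 + 1, j0, k0) * fi * (1 - fj) * (1 - fk) +
    idx(i0, j0 + 1, k0) * (1 - fi) * fj * (1 - fk) +
    idx(i0, j0, k0 + 1) * (1 - fi) * (1 - fj) * fk +
    idx(i0 + 1, j0 + 1, k0) * fi * fj * (1 - fk) +
    idx(i0 + 1, j0, k0 + 1) * fi * (1 - fj) * fk +
    idx(i0, j0 + 1, k0 + 1) * (1 - fi) * fj * fk +
    idx(i0 + 1, j0 + 1, k0 + 1) * fi * fj * fk
  out[ok] <- v
  out
}

# Separable FFT Gaussian smoothing of a 3D array (sigma in voxels, possibly
# per-axis).  Periodic wrap is harmless on background-padded stacks.
.vm_gauss_smooth3 <- function(arr, sigma) {
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  if (all(sigma <= 0)) return(arr)
  d <- dim(arr)
  tf <- function(n, sg) {
    if (sg <= 0) return(rep(1, n))
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sg^2))
    k <- k / sum(k)
    Re(stats::fft(k))
  }
  H <- outer(outer(tf(d[1], sigma[1]), tf(d[2], sigma[2])), tf(d[3], sigma[3]))
  dim(H) <- d
  Re(stats::fft(stats::fft(arr) * H, inverse = TRUE)) / prod(d)
}
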