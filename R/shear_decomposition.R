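# Decomposition of wall shear stress series into the three components
# sensed by endocardial cells: the time average tau0, the harmonic
# amplitudes tau_k of the phase-averaged (periodic) component, and the RMS
# nonperiodic residual tau'.  The beat period is an input (known from the
# wall kinematics); an autocorrelation-based estimator is provided for
# measured signals.

#' Phase average of a periodic signal
#'
#' Folds the series onto one beat period and averages per phase bin.  When a
#' sample's phase straddles two bins its weight is split linearly; a trailing
#' partial period is discarded with a warning.
#'
#' @param time sample times (uniformly spaced).
#' @param values sample values.
#' @param period beat period `T`.
#' @param bins number of phase bins (defaults to samples per period when
#'   that is an integer <= 128).
#' @return object of class `phase_average`: list with bin-center `phase`
#'   (in [0, T)), `curve`, `period`, `n_beats`.
#' @export
phase_average <- function(time, values, period, bins = NULL) {
  stopifnot(length(time) == length(values), period > 0)
  dt <- stats::median(diff(time))
  spp <- period / dt
  n_complete <- floor((length(time) + 1e-9) * dt / period)
  if (n_complete < 2) {
    stop("series must span at least 2 complete periods")
  }
  keep <- seq_len(round(n_complete * spp))
  if (length(keep) < length(time)) {
    warning(sprintf("discarding trailing partial period (%d samples)",
                    length(time) - length(keep)))
    time <- time[keep]
    values <- values[keep]
  }
  if (is.null(bins)) {
    bins <- if (abs(spp - round(spp)) < 1e-8) min(round(spp), 128) else 64
  }
  if (bins > spp + 1e-9) {
    stop("samples per period must be >= bins")
  }
  # bin centers at phases j/bins * period, j = 0..bins-1 (aligned with the
  # first sample so exact folds stay exact); samples whose phase straddles
  # two centers are split linearly between them
  ph <- ((time - time[1]) %% period) / period * bins # in [0, bins)
  b0 <- floor(ph + 1e-9)
  w1 <- ph - b0
  w1[w1 < 1e-9] <- 0
  bl <- (b0 %% bins) + 1
  br <- ((b0 + 1) %% bins) + 1
  acc <- numeric(bins)
  wacc <- numeric(bins)
  for (i in seq_along(values)) {
    acc[bl[i]] <- acc[bl[i]] + (1 - w1[i]) * values[i]
    wacc[bl[i]] <- wacc[bl[i]] + (1 - w1[i])
    acc[br[i]] <- acc[br[i]] + w1[i] * values[i]
    wacc[br[i]] <- wacc[br[i]] + w1[i]
  }
  structure(list(
    phase = (seq_len(bins) - 1) / bins * period,
    curve = acc / wacc,
    period = period,
    bins = bins,
    n_beats = n_complete,
    t0 = time[1]
  ), class = "phase_average")
}

#' Harmonic amplitudes of a phase-average curve
#'
#' Standard Fourier analysis of the one-period phase-average curve: `tau0`
#' is the curve mean and `tau_k` is scaled so a pure input
#' `A sin(2 pi k f1 t + phi)` yields `tau_k = A`.
#'
#' @param pa a [phase_average()] (or a bare numeric curve).
#' @param K number of harmonics (must satisfy `K < bins/2`).
#' @return list with `tau0`, `tau_k` (length `K`), `phase_k` (radians, sine
#'   convention), `K`.
#' @export
harmonic_amplitudes <- function(pa, K = 3) {
  curve <- if (inherits(pa, "phase_average")) pa$curve else as.numeric(pa)
  nb <- length(curve)
  if (K >= nb / 2) {
    stop("argument error: K must be < bins/2 (aliasing)")
  }
  co <- stats::fft(curve) / nb
  tau0 <- Re(co[1])
  ks <- seq_len(K)
  amp <- 2 * Mod(co[ks + 1])
  # curve = tau0 + sum_k amp_k sin(2 pi k p/P + phase_k); bin centers sit at
  # phases (j-1)/nb so the fft angle maps to the sine phase via + pi/2
  phs <- Arg(co[ks + 1]) + pi / 2
  phs <- ((phs + pi) %% (2 * pi)) - pi
  list(tau0 = tau0, tau_k = amp, phase_k = phs, K = K)
}

# evaluate the phase-average curve at arbitrary times by periodic linear
# interpolation between bin centers (centers at phases (j-1)/nb relative to
# the fold origin t0)
.vm_pa_eval <- function(pa, time, t0 = NULL) {
  if (is.null(t0)) t0 <- pa$t0
  P <- pa$period
  nb <- pa$bins
  ph <- ((time - t0) %% P) / P * nb
  b0 <- floor(ph + 1e-9)
  w <- ph - b0
  w[w < 1e-9] <- 0
  bl <- (b0 %% nb) + 1
  br <- ((b0 + 1) %% nb) + 1
  (1 - w) * pa$curve[bl] + w * pa$curve[br]
}

#' RMS nonperiodic component of a shear-stress series
#'
#' Root mean square of the deviation of the series from its periodic
#' component (the phase average), evaluated by periodic interpolation.
#'
#' @param time,values the series.
#' @param pa its [phase_average()] over the same period.
#' @return scalar `tau'`.
#' @export
nonperiodic_rms <- function(time, values, pa) {
  stopifnot(inherits(pa, "phase_average"))
  dt <- stats::median(diff(time))
  n_keep <- round(pa$n_beats * pa$period / dt)
  keep <- seq_len(min(n_keep, length(values)))
  tilde <- .vm_pa_eval(pa, time[keep], t0 = time[1])
  sqrt(mean((values[keep] - tilde)^2))
}

#' Decompose a wall shear stress record into spatial profiles
#'
#' Per-station time average `tau0`, harmonic amplitudes `tau_k` and phases
#' of the phase-averaged periodic component, and nonperiodic RMS `tau'`,
#' plus a normalized copy in which stresses are divided by the spatial mean
#' of the fundamental amplitude `tau1`.
#'
#' @param record a [wss_record()] (or any list with `time`, `tau` matrix,
#'   `stations`, `period`).
#' @param K harmonics reported.
#' @param bins phase bins.
#' @return object of class `wss_decomposition`: list with `stations`,
#'   `tau0`, `tau_k` (matrix `K x n_stations`), `phase_k`, `tau_np`,
#'   `phase_avg` (matrix `bins x n_stations`), `normalized` (scaled
#'   profiles), `period`, `K`.
#' @export
spatial_profiles <- function(record, K = 3, bins = NULL) {
  stopifnot(!is.null(record$tau), ncol(record$tau) >= 2)
  ns <- ncol(record$tau)
  pa1 <- phase_average(record$time, record$tau[, 1], record$period, bins)
  nb <- pa1$bins
  tau0 <- numeric(ns)
  tau_k <- matrix(0, K, ns)
  phase_k <- matrix(0, K, ns)
  tau_np <- numeric(ns)
  pav <- matrix(0, nb, ns)
  for (j in seq_len(ns)) {
    pa <- phase_average(record$time, record$tau[, j], record$period, nb)
    ha <- harmonic_amplitudes(pa, K)
    tau0[j] <- ha$tau0
    tau_k[, j] <- ha$tau_k
    phase_k[, j] <- ha$phase_k
    tau_np[j] <- nonperiodic_rms(record$time, record$tau[, j], pa)
    pav[, j] <- pa$curve
  }
  scale <- mean(tau_k[1, ])
  structure(list(
    stations = record$stations,
    tau0 = tau0, tau_k = tau_k, phase_k = phase_k, tau_np = tau_np,
    phase_avg = pav, phase = pa1$phase,
    period = record$period, K = K, bins = nb,
    tau1_space_mean = scale,
    normalized = list(
      tau0 = tau0 / scale,
      tau_k = tau_k / scale,
      tau_np = tau_np / scale
    )
  ), class = "wss_decomposition")
}

#' @export
print.wss_decomposition <- function(x, ...) {
  cat(sprintf("WSS decomposition: %d stations, K = %d harmonics\n",
              length(x$stations), x$K))
  cat(sprintf("  tau1 peak at x = %.3g; spatial mean tau1 = %.3g\n",
              x$stations[which.max(x$tau_k[1, ])], x$tau1_space_mean))
  invisible(x)
}

#' Signed spatial gradient of the fundamental harmonic amplitude
#'
#' Central divided differences of `tau1` on the station grid (one-sided at
#' the ends); positive values point toward +x.
#'
#' @param decomp a [spatial_profiles()] result.
#' @param periodic treat the station grid as periodic (default TRUE for the
#'   periodic tube).
#' @return numeric vector, one gradient per station.
#' @export
gradient_tau1 <- function(decomp, periodic = TRUE) {
  x <- decomp$stations
  v <- decomp$tau_k[1, ]
  n <- length(x)
  stopifnot(n >= 3)
  g <- numeric(n)
  if (periodic) {
    # assume stations cover one period uniformly
    Lx <- n * stats::median(diff(x))
    xm <- c(x[n] - Lx, x, x[1] + Lx)
    vm <- c(v[n], v, v[1])
    for (i in seq_len(n)) {
      g[i] <- (vm[i + 2] - vm[i]) / (xm[i + 2] - xm[i])
    }
  } else {
    g[1] <- (v[2] - v[1]) / (x[2] - x[1])
    g[n] <- (v[n] - v[n - 1]) / (x[n] - x[n - 1])
    for (i in 2:(n - 1)) {
      g[i] <- (v[i + 1] - v[i - 1]) / (x[i + 1] - x[i - 1])
    }
  }
  g
}

#' Estimate the beat period of a measured signal
#'
#' Parabolic refinement of the first significant peak of the sample
#' autocorrelation.  For simulated records the known wall-motion period
#' should be used instead.
#'
#' @param time,values the series.
#' @return estimated period.
#' @export
estimate_period <- function(time, values) {
  dt <- stats::median(diff(time))
  v <- values - mean(values)
  ac <- stats::acf(v, lag.max = floor(length(v) / 2), plot = FALSE)$acf[, 1, 1]
  # first local max after the initial decay below zero
  below <- which(ac < 0)
  if (length(below) == 0) stop("no periodicity detected")
  start <- below[1]
  seg <- ac[start:length(ac)]
  pk <- which.max(seg) + start - 1
  if (pk <= 1 || pk >= length(ac)) stop("no periodicity detected")
  # parabolic interpolation around the peak (lags are 0-based: index i is lag i-1)
  y1 <- ac[pk - 1]; y2 <- ac[pk]; y3 <- ac[pk + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
  ((pk - 1) + delta) * dt
}
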