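# Moving geometry of the heart tube: a linear 2D channel, periodic in x, with
# an atrium, a narrowed atrioventricular canal (AVC), and a ventricle.  The
# walls displace harmonically with amplitude and phase profiles along the
# tube; phase-lagged contraction of the two chambers makes the tube a
# valveless pump.
#
# Nondimensionalization: lengths in units of the chamber rest half-width,
# time in units of the beat period T = 1/f1, viscosity mu = 1.  Stresses are
# therefore in units of mu * f1.

# smooth C^1 plateau bump: 1 on |u| <= flat/2, cosine ramp to 0 over `ramp`
.vm_bump <- function(u, flat, ramp) {
  a <- abs(u)
  out <- numeric(length(u))
  out[a <= flat / 2] <- 1
  sel <- a > flat / 2 & a < flat / 2 + ramp
  out[sel] <- 0.5 * (1 + cos(pi * (a[sel] - flat / 2) / ramp))
  out
}

# periodic distance to a center
.vm_pdist <- function(x, center, L) {
  d <- (x - center) %% L
  ifelse(d > L / 2, d - L, d)
}

#' Define the rest geometry of the heart tube
#'
#' The tube is a straight channel of axial period `length` (one spatial
#' period), symmetric about the centerline, with rest half-width 1 in the
#' chambers and a smooth constriction of minimum half-width `avc_half_width`
#' at the AVC.  All lengths are in units of the chamber rest half-width.
#'
#' @param length axial period of the tube.
#' @param avc_half_width minimum rest half-width of the AVC constriction
#'   (must be in (0, 1)).
#' @param avc_center axial position of the AVC center.
#' @param avc_flat length of the flat (fully constricted) AVC section.
#' @param avc_ramp length of each smooth transition flanking the AVC.
#' @return an object of class `tube_geometry` with the half-width profile
#'   `h0(x)` and labeled segment extents (`atrium`, `avc`, `ventricle`).
#' @examples
#' geom <- tube_geometry()
#' curve(geom$h0(x), 0, geom$length, ylab = "h0(x)")
#' @export
tube_geometry <- function(length = 8, avc_half_width = 0.4, avc_center = NULL,
                          avc_flat = 0.8, avc_ramp = 0.8) {
  stopifnot(length > 0, avc_half_width > 0, avc_half_width < 1,
            avc_flat >= 0, avc_ramp > 0)
  if (is.null(avc_center)) avc_center <- length / 2
  half_extent <- avc_flat / 2 + avc_ramp
  if (2 * half_extent >= length) {
    stop("AVC constriction does not fit inside the tube period")
  }
  L <- length
  h0 <- function(x) {
    u <- .vm_pdist(x, avc_center, L)
    1 - (1 - avc_half_width) * .vm_bump(u, avc_flat, avc_ramp)
  }
  structure(list(
    length = L,
    avc_half_width = avc_half_width,
    avc_center = avc_center,
    h0 = h0,
    segments = list(
      avc = c(avc_center - half_extent, avc_center + half_extent),
      atrium = c(0, avc_center - half_extent),
      ventricle = c(avc_center + half_extent, L)
    )
  ), class = "tube_geometry")
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat("Heart tube geometry (periodic channel)\n")
  cat(sprintf("  period: %.3g half-widths, AVC half-width %.3g at x = %.3g\n",
              x$length, x$avc_half_width, x$avc_center))
  cat(sprintf("  AVC segment: [%.3g, %.3g]\n",
              x$segments$avc[1], x$segments$avc[2]))
  invisible(x)
}

#' Define harmonic wall motion for a tube geometry
#'
#' The upper wall is at `y = h0(x) - a(x) * (1 + sin(2 pi f1 t - phi(x))) / 2`
#' and the lower wall mirrors it when `symmetric = TRUE`.  The default
#' "two-chamber pump" preset gives the atrium and ventricle each a smooth
#' amplitude bump, with the ventricular phase lagging the atrial phase by
#' `dphi`; the phase-lagged contraction drives net atrium-to-ventricle
#' pumping at zero Reynolds number.
#'
#' Because the channel is axially periodic, an incompressible interior
#' requires the enclosed area to be constant in time.  The raw harmonic
#' profile does not guarantee this for arbitrary phase profiles, so a
#' spatially uniform, time-periodic, zero-mean offset `c(t)` can be added to
#' both walls (`volume_correction = TRUE`, used by the flow solver).  Direct
#' calls default to the raw profile.
#'
#' @param geometry a [tube_geometry()].
#' @param amplitude either a function `a(x)` or `"two_chamber"` for the
#'   preset.
#' @param phase either a function `phi(x)` (radians) or `"two_chamber"`.
#' @param f1 fundamental (beat) frequency; the beat period is `T = 1/f1`.
#' @param symmetric mirror the motion of the two walls.
#' @param chamber_amplitude preset chamber bump peak amplitudes
#'   `c(atrial, ventricular)` (a scalar is used for both).
#' @param avc_amplitude preset amplitude of the AVC constriction's own
#'   oscillation.
#' @param avc_phase preset phase of the AVC oscillation (radians).
#' @param dphi ventricular phase lag in radians (preset, default 2.2).
#' @param asymmetry multiplicative amplitude factor for the lower wall when
#'   `symmetric = FALSE`.
#' @return an object of class `wall_motion`.
#' @examples
#' mot <- wall_motion(tube_geometry())
#' wall_position(mot, x = 2, t = 0.25, side = "upper")
#' @export
wall_motion <- function(geometry, amplitude = "two_chamber",
                        phase = "two_chamber", f1 = 1, symmetric = TRUE,
                        chamber_amplitude = c(0.35, 0.5),
                        avc_amplitude = 0.25, avc_phase = 0.3,
                        dphi = 2.2, asymmetry = 1) {
  stopifnot(inherits(geometry, "tube_geometry"), f1 > 0)
  L <- geometry$length
  cA <- mean(geometry$segments$atrium)
  cV <- mean(geometry$segments$ventricle)
  wA <- diff(geometry$segments$atrium)
  wV <- diff(geometry$segments$ventricle)
  if (is.character(amplitude) && amplitude == "two_chamber") {
    # The preset superposes three harmonic oscillators in the complex plane
    # (amplitude * exp(-i phase)): the atrium at phase 0, the ventricle
    # lagging by dphi, and the AVC constriction at its own phase avc_phase.
    # The pointwise modulus/argument give smooth periodic a(x), phi(x)
    # profiles; all three bumps vanish at the periodic junction.
    aA <- if (length(chamber_amplitude) == 2) chamber_amplitude[1] else
      chamber_amplitude
    aV <- if (length(chamber_amplitude) == 2) chamber_amplitude[2] else
      chamber_amplitude
    complex_profile <- function(x) {
      bumpA <- .vm_bump(.vm_pdist(x, cA, L), 0.3 * wA, 0.25 * wA)
      bumpV <- .vm_bump(.vm_pdist(x, cV, L), 0.3 * wV, 0.25 * wV)
      avc <- .vm_bump(.vm_pdist(x, geometry$avc_center, L),
                      diff(geometry$segments$avc) * 0.4,
                      diff(geometry$segments$avc) * 0.3)
      aA * bumpA + aV * bumpV * exp(-1i * dphi) +
        avc_amplitude * avc * exp(-1i * avc_phase)
    }
    a_fun <- function(x) {
      pmin(Mod(complex_profile(x)), 0.88 * geometry$h0(x))
    }
  } else {
    stopifnot(is.function(amplitude))
    a_fun <- amplitude
  }
  if (is.character(phase) && phase == "two_chamber") {
    if (!is.character(amplitude)) {
      stop("the 'two_chamber' phase preset requires the matching amplitude ",
           "preset")
    }
    phi_fun <- function(x) -Arg(complex_profile(x))
  } else {
    stopifnot(is.function(phase))
    phi_fun <- phase
  }
  # construction-time check: walls must never cross the centerline
  xs <- seq(0, L, length.out = 512)
  if (any(a_fun(xs) >= geometry$h0(xs))) {
    stop("configuration error: amplitude a(x) >= rest half-width h0(x)")
  }
  obj <- structure(list(
    geometry = geometry, a = a_fun, phi = phi_fun, f1 = f1, T = 1 / f1,
    symmetric = symmetric, asymmetry = asymmetry
  ), class = "wall_motion")
  obj
}

.vm_smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# instantaneous area offset c(t) making the enclosed channel area constant
# (volume-conserving gauge for the periodic closure); zero time mean
.vm_area_offset <- function(motion, t) {
  L <- motion$geometry$length
  xs <- seq(0, L, length.out = 513)[-513]
  a <- motion$a(xs)
  phi <- motion$phi(xs)
  vapply(t, function(tt) {
    mean(a * sin(2 * pi * motion$f1 * tt - phi)) / 2
  }, numeric(1))
}

#' Wall position of the moving tube
#'
#' @param motion a [wall_motion()].
#' @param x axial stations (numeric vector).
#' @param t time (scalar or vector recycled against `x`).
#' @param side `"upper"` or `"lower"`.
#' @param volume_correction add the spatially uniform offset that keeps the
#'   enclosed area constant in time (required by the periodic flow solver).
#' @return transverse wall coordinate(s).
#' @export
wall_position <- function(motion, x, t, side = c("upper", "lower"),
                          volume_correction = FALSE) {
  side <- match.arg(side)
  stopifnot(inherits(motion, "wall_motion"))
  a <- motion$a(x)
  phi <- motion$phi(x)
  disp <- a * (1 + sin(2 * pi * motion$f1 * t - phi)) / 2
  off <- if (volume_correction) .vm_area_offset(motion, t) else 0
  if (side == "upper") {
    motion$geometry$h0(x) - disp + off
  } else {
    amp <- if (motion$symmetric) 1 else motion$asymmetry
    -(motion$geometry$h0(x) - amp * disp + off)
  }
}

#' Wall velocity of the moving tube
#'
#' Exact time derivative of [wall_position()]; has zero time average at
#' every station.
#'
#' @inheritParams wall_position
#' @return transverse wall material velocity.
#' @export
wall_velocity <- function(motion, x, t, side = c("upper", "lower"),
                          volume_correction = FALSE) {
  side <- match.arg(side)
  stopifnot(inherits(motion, "wall_motion"))
  a <- motion$a(x)
  phi <- motion$phi(x)
  w <- 2 * pi * motion$f1
  ddisp <- a * w * cos(w * t - phi) / 2
  doff <- 0
  if (volume_correction) {
    L <- motion$geometry$length
    xs <- seq(0, L, length.out = 513)[-513]
    doff <- vapply(t, function(tt) {
      mean(motion$a(xs) * w * cos(w * tt - motion$phi(xs))) / 2
    }, numeric(1))
  }
  if (side == "upper") {
    -ddisp + doff
  } else {
    amp <- if (motion$symmetric) 1 else motion$asymmetry
    amp * ddisp - doff
  }
}

#' @export
print.wall_motion <- function(x, ...) {
  cat("Harmonic wall motion\n")
  cat(sprintf("  f1 = %.3g (T = %.3g), %s walls\n", x$f1, x$T,
              if (x$symmetric) "mirror-symmetric" else "asymmetric"))
  invisible(x)
}
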