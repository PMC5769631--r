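---
title: "Models and methods behind valvemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind valvemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`valvemorph` studies the mechanical environment of the forming
atrioventricular canal (AVC) in a tubular embryonic heart from two sides: a
computational-biomechanics side, which simulates blood flow in a beating
valveless heart tube and decomposes the wall shear stress that endocardial
cells experience, and an image-analysis side, which quantifies the
convergence of photolabeled endocardial tissue toward the AVC from
two-timepoint 3D stacks. This vignette explains the models, the numerical
choices, the defaults and what they do (and do not) demonstrate.

## The heart tube and its motion

The heart is modeled as a two-dimensional channel, axially periodic with
period `L` (default 8), symmetric about the centerline. All lengths are in
units of the chamber rest half-width, time in units of the beat period
(fundamental frequency `f1 = 1`) and the viscosity is 1, so stresses are in
units of `mu * f1`. The rest half-width profile `h0(x)` is 1 in the atrium
and ventricle and dips smoothly to `avc_half_width` (default 0.4) in the
AVC constriction, with cosine ramps (`tube_geometry()`).

Each wall displaces harmonically,

```
y_upper(x, t) = h0(x) - a(x) * (1 + sin(2*pi*f1*t - phi(x))) / 2 ,
```

with the lower wall mirrored. The default "two-chamber pump" preset builds
the amplitude and phase profiles by superposing three oscillators in the
complex plane — atrium (phase 0), ventricle (lagging by `dphi`) and the AVC
constriction itself (phase `avc_phase`) — and taking the pointwise modulus
and argument. This guarantees smooth, periodic `a(x)`, `phi(x)` with no
seam at the periodic junction, where all three amplitude bumps vanish.

The preset defaults (`chamber_amplitude = c(0.35, 0.5)`,
`avc_amplitude = 0.25`, `avc_phase = 0.3`, `dphi = 2.2`) were fixed once,
from a kinematic design study performed before any acceptance checking, as
the combination that places the simulated tube in the physiological regime
reported for the 36–48 hpf zebrafish heart: strongly oscillatory,
frequently reversing AVC flow; a small positive (atrium-to-ventricle) mean
flux; the fundamental shear-stress harmonic peaking inside the AVC; and a
time-average shear stress pointing away from the AVC on both flanks. Two
mechanisms matter here. The phase-lagged chambers provide net valveless
pumping; the AVC's own near-standing oscillation acts as a rectifier whose
steady streaming produces the characteristic outward `tau0` dipole around
the constriction. A fully mirror-symmetric configuration (equal chamber
amplitudes with an antisymmetric phase profile) maps onto its own time
reversal, which forces `tau0(x) = tau0(L - x)` exactly and can never show
the dipole; the unequal chamber amplitudes deliberately break that
symmetry. The measured amplitude/phase profiles of a real heart can be
supplied instead, either as R functions or as tabulated `(x, a, phi)`
triples in the configuration file.

**Periodic closure.** Because the channel is periodic, incompressibility
requires the enclosed area to be constant in time, which the raw harmonic
formula does not guarantee for general phase profiles. The flow solver
therefore adds a spatially uniform, time-periodic, zero-mean offset `c(t)`
to both walls (the *volume-conserving gauge*; `volume_correction = TRUE`).
Direct calls to `wall_position()` default to the raw formula.

## The flow solver

At the scales of the embryonic heart the Reynolds number is well below 1,
so the model contains no inertia anywhere: at every instant the Stokes
equations are solved afresh given the current boundary motion and membrane
forces. The solver is a boundary-integral method of regularized Stokeslets
in a singly periodic 2D domain:

* The axial periodicity is exact: the kernel is the closed-form singly
  periodic Stokeslet (built from the harmonic potential
  `A = log|2(cosh k y - cos k x)|/2`, `k = 2*pi/L`), corrected from
  singular to regularized form for the principal copy and the nearest
  `n_images` (default 3) periodic images. The remaining truncation error is
  a few parts in 10^4 of the kernel scale, far below the discretization
  error, because of the composite blob described next.
* **Composite blob.** A single algebraic blob
  `phi_eps = eps^2 / (pi (r^2 + eps^2)^2)` produces two first-order error
  terms: a slowly decaying `eps^2/r^2` far tail (its second moment
  diverges) and an `O(eps)` effective slip at a flat force layer, which
  biases wall tractions by several percent at practical resolutions. The
  solver therefore combines three scaled copies of the blob (scales 1, 1.5,
  2.25 with weights 5.4, -6, 1.6) chosen so that both the far-tail
  coefficient and the flat-layer slip cancel. Plane Couette and plane
  Poiseuille tractions are then recovered to ~0.01% at 128 collocation
  points per wall; the acceptance suite verifies 1%.
* **Traction.** Wall traction is evaluated from the analytic stress kernels
  (pressure plus velocity-gradient kernels) on the wall, which yields the
  average of the two one-sided stresses across the force layer, plus half
  the local traction jump (the local force density). The reported `tau` is
  the tangential traction the fluid exerts on the wall, positive toward +x
  (atrium to ventricle); the normal traction is reported alongside and
  shows no comparable patterning.
* The mean pressure gradient of the periodic channel is zero by default
  (pumping arises from wall motion only); an imposed gradient or a mean
  flux constraint is available for validation flows.
* A constant "gauge" added to the kernel diagonal (a uniform-flow gauge of
  the 2D Green's function, size `1 + k * max|y|`) keeps the net-force mode
  of the mobility matrix well conditioned; it does not affect tractions or
  relative flows.

Degenerate configurations are reported, not patched: a singular mobility
matrix names the translation null mode, and `eps` below a tenth of the
collocation spacing triggers an ill-conditioning warning.

## Red blood cells

Each cell is a closed discretized curve with stretching and bending
resistance,

```
E = (k_s/2) * sum (|l_i|/|l0_i| - 1)^2 |l0_i| + (k_b/2) * sum theta_i^2 / ds0_i ,
```

where `theta_i` is the turning angle at node `i`. Forces are the exact
negative gradient of `E`, so the force set is translation- and
rotation-free to round-off (verified against finite differences). This
minimal elastic-shell model reproduces the qualitative behaviors of
confined capsule suspensions (deformation in shear, near-wall depletion)
without claiming a specific constitutive law; there is no viscosity
contrast between the cell interior and the plasma, which keeps the
boundary-integral formulation single-layer only.

Defaults: rest ellipse of aspect ratio 2 with effective radius
`sqrt(a b) = 0.2`, i.e. half the AVC rest half-width, matching the
observation that embryonic red blood cells squeeze through the canal;
`k_s = 5`, `k_b = 0.01` (nondimensional, sized so membrane relaxation is
fast compared to the beat but explicit stepping at the default time step is
stable); 32 nodes per cell. A short-range repulsion (cutoff 0.08) prevents
numerical overlap between cells and with the walls; it is a numerical
regularization, not a physical contact model. Cells are reseeded
reproducibly from the configuration seed by rejection sampling in the
atrial segment (or any configured set of axial intervals — the
cell-number sweeps seed both chambers, since twenty cells exceed the
atrium's capacity).

Mesh quality over long runs is maintained by periodic-spline
reparameterization at equal arc length every `reparam_every` steps,
followed by a uniform rescaling about the centroid that restores the
enclosed polygon area exactly; enclosed areas then drift by well under 1%
over multi-beat runs.

## Time integration and recording

A Heun predictor-corrector advances membrane nodes; each stage rebuilds the
wall mesh at the stage time and re-solves the mobility system with the
known membrane forces. Records (wall shear stress and normal traction at
uniformly spaced axial stations on both walls, cross-sectional fluxes, cell
centroids and outlines) are sampled `samples_per_beat` times per beat; the
first `discard_beats` beats (default 2) are excluded from all statistics so
phase averaging sees a statistically periodic signal.

Reference resolutions: the package default is 128 points per wall, 200
steps per beat, 32 nodes per cell and 8 beats. The shipped tests and the
acceptance script use reduced sizes chosen to keep full runs at minutes on
a single core — 72 to 80 points per wall and steps per beat over 6 beats
for the cell-free reference runs, and 64 points per wall, 60 steps per beat,
20 nodes per cell over 3 beats for the cell-number sweeps — after checking
that the qualitative pattern is unchanged between these resolutions.

## Shear-stress decomposition

For each station the series `tau(t)` is split into the time average
`tau0`, the harmonics of the phase-averaged (periodic) component, and the
nonperiodic residual:

* `phase_average()` folds the series onto the known beat period (the period
  is an input in the simulation context; an autocorrelation estimator is
  provided for measured signals) into bins whose centers are aligned with
  the sample phases, so integer-beat records fold exactly; samples
  straddling bin centers are split linearly.
* `harmonic_amplitudes()` applies standard Fourier analysis to the folded
  curve; `tau_k` is scaled so a pure `A sin(2 pi k f1 t + phi)` input gives
  `tau_k = A`. Requesting `K >= bins/2` harmonics is an aliasing error.
* `nonperiodic_rms()` is the RMS deviation of the raw series from the
  periodically interpolated phase average. For a periodic signal plus white
  noise of standard deviation `sigma` over `N` beats it converges to
  `sigma * sqrt(1 - 1/N)`; for a noiseless cell-free simulation it is zero
  to solver precision.
* `spatial_profiles()` assembles per-station profiles and a normalized copy
  in which stresses are divided by the spatial mean of the fundamental
  amplitude `tau1` (the scaling used when comparing profile shapes), and
  `gradient_tau1()` gives the signed spatial derivative of `tau1` by
  central differences (periodic by default on the periodic station grid).

The variance identity
`mean(tau^2) = tau0^2 + (1/2) sum tau_k^2 + tau'^2` holds to 10^-6
relative for integer beats, bins equal to samples per beat and
`K = bins/2 - 1`, provided the nonperiodic part is band limited (white
noise leaves exactly the Nyquist-mode term, which the `K`-sum cannot
represent).

`report_directions()` condenses a decomposition into the directional
summary used throughout: the sign of `tau0` on the atrial and ventricular
flanks of the AVC (flanks are the stations within one sixth of the AVC
segment length of its boundaries), the sign of the `tau1` gradient on each
flank, the peak station of `tau1`, and the sign of the mean flux. In the
default cell-free simulation the mean flow is atrium-to-ventricle while
`tau0` points *away* from the AVC on both flanks and the `tau1` gradient
points *toward* it — the flow direction a tissue would read from the mean
shear disagrees with the actual mean flow direction, which is the central
qualitative prediction the simulation stage exists to reproduce.

## Synthetic data

`make_signal()` generates shear-stress series with prescribed constant,
harmonic, per-beat amplitude-jitter and white-noise content (the jitter is
the band-limited stand-in for the beat-to-beat variability that cells
introduce). `make_phantom()` generates two-channel 3D stacks of a curved
tube: a structural ("green") intensity shell along the whole tube and a
photoconverted ("red") label restricted to two axial bands flanking an
unlabeled gap of prescribed arc length per timepoint, with an optional
sinusoidal per-azimuth modulation of the gap. The shell is a hard-edged
annulus smoothed by a one-voxel Gaussian, so sub-voxel edge localization is
meaningful but controlled. What the phantoms deliberately do not emulate:
myocardial texture, beating-motion blur, photobleaching, anisotropic
point-spread functions. Passing the recovery tests therefore demonstrates
the correctness of the geometry pipeline, not robustness to every
real-microscope artifact.

## Tube unfolding and shortening

`fit_centerline()` refines user seed points by iterated intensity-weighted
centroiding (the centroid of a shell ring lies on the axis) and fits a
smooth arc-length-parameterized curve; frames are transported along it by
the rotation-minimizing double-reflection method, then rotated so azimuth
zero tracks a configurable anatomical reference direction (quadrant labels
are anatomical, so this mapping must come from the user). Near the tube
ends the centroid windows are one-sided and biased; analyses exclude a
margin (the tests validate the fitted radius of a quarter-torus phantom on
the interior span, where it is exact to 1%).

`unfold()` casts radial rays on an (arc length x azimuth) grid, locates the
shell at the parabolic-refined peak of the structural channel, and projects
each channel as the maximum within a radial band around the shell. Rays
that exit the stack are flagged missing, never zero-filled. `measure_L()`
smooths each azimuth column of the red channel, thresholds at half of the
column's band plateau (robust to plateau-level variation), and returns the
arc-length distance between the inner band edges with sub-sample linear
interpolation — the length of the *nonphotoconverted* gap. A fully
photoconverted column reports zero; columns with fewer than two detected
bands report missing values and are counted.

`shortening()` forms `(L2 - L1)/L1` per azimuth (negative values mean the
labeled regions moved closer: tissue convergence) and averages over four
90-degree quadrants, labeled `a` (superior), `b` (exterior), `c`
(inferior), `d` (interior) at a configurable angular offset, excluding
missing azimuths and flagging empty quadrants. Coordinates follow
voxel-index-times-spacing conventions with half-open intervals throughout.

## Group statistics

`t_test_unpaired()` is the classic pooled-variance two-sample Student test
(two-tailed, `df = nA + nB - 2`), with Welch's correction behind a flag;
p values come from the t distribution and are regression-tested against an
independent implementation and a textbook critical value, and the null
rejection rate is calibrated at the nominal 5%. Quadrants are tested
individually with no multiple-testing correction, which the output
metadata states explicitly.

## Reproducibility

Every stochastic component (cell seeding, synthetic noise, phantom noise)
draws from an explicit integer seed, and `run_pipeline()` expands one root
seed deterministically per stage, records per-stage seeds, a config hash
and MD5 checksums of every output in `manifest.json`, and re-runs
bit-identically from the same configuration and seed.

## Known limitations

The model is two-dimensional with kinematically driven walls: no wall
elasticity, no three-dimensional geometry, no azimuthal flow structure, and
therefore no statement about tissue strain or normal-force patterning. The
preset kinematics are a designed minimal pump, not measured heart-wall
kinematics; conclusions are pattern-level (signs, peak locations,
monotonic trends), never numeric stress values of a real heart. The
repulsion term regularizes near contact rather than modeling it, and cell
stiffness sweeps are expressed in nondimensional ratios only.
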