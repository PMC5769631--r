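Package: valvemorph
Title: Valveless-Pump Hemodynamics and Tissue Convergence in the Embryonic Heart
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the mechanics of early heart valve formation in a
    tubular embryonic heart. Simulates zero-Reynolds-number blood flow in a
    two-dimensional valveless pumping tube with harmonically moving walls and
    deformable red blood cells, using a singly-periodic regularized Stokeslet
    boundary integral method. Decomposes the resulting wall shear stress into
    its time average, harmonic amplitudes of the phase-averaged (periodic)
    component, and the root-mean-square nonperiodic residual. Quantifies
    tissue convergence from two-timepoint, two-channel 3D image stacks of a
    photolabeled heart tube by centerline fitting, cylindrical unfolding, and
    per-azimuth measurement of the unlabeled gap length, and compares
    quadrant-level shortening factors between experimental groups. Includes
    synthetic-data generators (tube image phantoms with known ground truth and
    shear-stress signals with known spectral content) so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
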