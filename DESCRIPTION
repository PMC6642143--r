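Package: tubupol
Title: Shape, Dipole and Electric-Field Polarization Analysis of Protein Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics trajectories of
    highly charged proteins, built around the tubulin heterodimer exposed to
    intense nanosecond electric fields. Fits a per-frame ellipsoid to the atom
    cloud by eigen-decomposition of the positional covariance matrix, derives a
    sign-continuous internal (body-fixed) coordinate frame that strips
    roto-translational motion, and computes electric dipole moments (whole
    protein, C-terminal tails, binding-site residues, single residues) in that
    frame. Includes segment statistics for time series, per-residue dipolar
    shift maps between field-exposed and reference runs, coil-count
    bookkeeping for externally assigned secondary structure, a quadratic
    dipole-dipole microtubule-lattice energy model, population statistics for
    protein charge/dipole data sets, and a synthetic rigid-rotor-plus-flexible-
    tail trajectory generator with exact ground truth for validating every
    pipeline stage without running molecular dynamics.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
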