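Package: cholbench
Title: Quality Evaluation of POPC-Cholesterol Membrane Simulations Against
    NMR and X-Ray Scattering Observables
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to benchmark molecular dynamics simulations of binary
    phosphatidylcholine-cholesterol bilayers against experimental reference
    data across cholesterol concentrations.  Implements C-H bond order
    parameter preprocessing (equivalent-hydrogen averaging with the oleate-C2
    fork exception), electron density smoothing, bilayer thickness from
    density maxima, X-ray form factors by Fourier transform and their minima
    tracking, area per phospholipid with block-averaged errors, the partial
    molecular area of cholesterol, finite-size (periodic Saffman-Delbrueck)
    correction of lateral diffusion coefficients with membrane shear
    viscosity estimation and Monte-Carlo error propagation, linear
    interpolation of observables over cholesterol concentration, and the
    assembly of per-observable relative deviations into a cumulative
    force-field quality report.  Synthetic generators with known ground
    truth make the full pipeline testable without trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
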