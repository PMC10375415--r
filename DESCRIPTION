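Package: protorec
Title: Proton Dose-Range Verification from Scattered-Proton Detector Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulation and reconstruction toolkit for in-beam
    proton dose-range verification with scintillation detectors. Provides a
    condensed-history Monte Carlo forward model (Bethe-Bloch slowing down,
    Highland multiple scattering, Bohr energy straggling, Rutherford
    hard-scatter sampling) over voxel phantoms, scintillator-array current
    readouts with an expected-value point-detector estimator, synthetic
    phantom and beam generators for three stepwise study families, a fully
    connected encoder-decoder that reconstructs the dose distribution
    from detector currents (optionally conditioned on the phantom density
    grid), and quantitative evaluation: Bragg-peak position errors,
    root-sum-squared dose error on a 100 Gy normalization, and 3D gamma
    analysis with configurable criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
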