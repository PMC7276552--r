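Package: photocolony
Title: Photonic Analysis of Structurally Coloured Bacterial Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring the nanoscale self-organization of
    structurally coloured bacterial colonies from their optical response.
    Implements inverse analysis of angle-resolved scattering goniometry
    (lattice-constant retrieval from the grating equation, average
    refractive index from the dispersion of the specular reflection,
    extraction and incidence-angle correction of domain-tilt diffraction
    streaks), forward photonic models (1D transfer-matrix reflectance of
    effective-index multilayers, 2D plane-wave-expansion band structure of
    the hexagonal cell lattice with mode-symmetry classification and
    partial-gap finding, and a compiled 2D finite-difference time-domain
    solver for angle-integrated reflectance of arbitrary disk ensembles),
    structure-factor and autocorrelation analysis of electron-microscopy
    style images, and generation of hard-disk packings with controlled
    positional and orientational disorder via structure-factor-targeted
    simulated annealing. Synthetic goniometer maps and cross-section images
    with known ground truth make every stage testable without experimental
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
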