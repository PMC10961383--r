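Package: holoqpi
Title: Off-Axis Digital Holographic Microscopy Simulation, Reconstruction
    and Cell Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and quantitative analysis of off-axis digital
    holographic microscopy (DHM) of cell monolayers on porous transwell
    membranes, as used for in-vitro blood-brain-barrier insert models.
    Generates ground-truth synthetic scenes (spherical-cap cells, porous
    membrane, treatment effects), renders realistic off-axis holograms
    (angular-spectrum propagation, carrier fringes, detector noise and
    quantization), reconstructs quantitative phase and 3-D height maps
    (Fourier sideband demodulation, optimal reference selection, numerical
    autofocus, circular median filtering, reliability-sorted phase
    unwrapping), and quantifies morphometry (per-cell volume, count,
    coverage, pore statistics) and treatment statistics (percent volume
    decrease, Welch comparisons, flow-cytometry-style uptake gating).
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
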