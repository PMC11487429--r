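Package: panelpet
Title: Desk-Scale Simulation and TOF-MLEM Reconstruction for Flat-Panel PET Design Studies
Version: 0.1.0
Authors@R: person("panelpet", "maintainers", email = "panelpet@example.org", role = c("aut", "cre"))
Description: Tools for comparative design studies of time-of-flight positron
    emission tomography (TOF-PET) scanners built from flat detector panels
    against a conventional cylindrical reference scanner. Provides a
    simplified Monte Carlo simulator for back-to-back 511 keV annihilation
    photons (phantom Compton scatter, crystal interaction physics, energy and
    timing blur), a digitizer and coincidence sorter with crystal- or
    submodule-level readout, a list-mode TOF-MLEM reconstructor with a Siddon
    ray-driven projector, and the standard performance metrics: 3D Gaussian
    spatial resolution fits, NEMA NU 2-2018 image quality with normalization
    correction, axial sensitivity profiles, noise-equivalent count rates
    (NECR and TOF-effective NECR) and the structural similarity index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
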