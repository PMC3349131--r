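Package: fusbioheat
Title: Discrete-Vessel Bioheat Simulation of Focused-Ultrasound Heating
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Finite-volume simulation of tissue heating by focused ultrasound
    in the presence of thermally significant blood vessels. Solves the
    two-domain bioheat model (enhanced-conductivity conduction in tissue,
    convection-diffusion with a parabolic velocity profile in straight vessel
    lumens) under a separable Gaussian power-deposition field, accumulates
    CEM43 thermal dose, and simulates multi-insonation treatment delivery
    (random, sequential raster and spiral trajectories) with fixed or
    dose-capped per-insonation power.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
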