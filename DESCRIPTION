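Package: tirftrack
Title: Simulation and Analysis of Single-Molecule TIRF Recordings of
    Membrane Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-molecule total internal reflection
    fluorescence (TIRF) microscopy of membrane receptors. Simulates
    calibrated TIRF movies of diffusing, photobleaching, reversibly
    dimerizing receptors with ground-truth particle histories; detects
    diffraction-limited spots and links them into trajectories; estimates
    lateral diffusion coefficients from mean-squared-displacement curves
    and classifies the mode of motion; scores oligomeric state from
    stepwise photobleaching of spot intensity traces; estimates receptor
    surface density by direct spot counting and by photobleaching-rate
    extrapolation; models equilibrium ligand occupancy and competition
    binding; and predicts receptor-channel encounter rates and
    first-collision latencies with a two-dimensional Monte Carlo collision
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
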