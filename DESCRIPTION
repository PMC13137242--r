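Package: hbidyn
Title: Multiple-Spawning Nonadiabatic Dynamics and Time-Resolved
    Photoelectron Spectra on a Branching-Plane Model of the GFP
    Chromophore Anion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating the ultrafast UV response of the
    deprotonated green fluorescent protein (GFP) chromophore anion (HBI)
    at desk scale.  A calibrated two-coordinate diabatic vibronic model
    (shape and Feshbach resonance diabats with linear Jahn-Teller-type
    coupling, a spectator bright state and the neutral D0 surface)
    stands in for ab initio electronic structure.  The package provides
    harmonic Wigner-distribution sampling of initial conditions with a
    vertical-energy-gap window, frozen-Gaussian full-multiple-spawning
    wavepacket propagation with adaptive time steps and step-rejection
    rules, adiabatic and state-character population analysis, simulated
    time-resolved photoelectron spectra (TRPES) with Dyson-norm
    intensity weighting and 2D Gaussian convolution, critical-point and
    minimal-energy conical intersection location, and seeded synthetic
    fixtures with known ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
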