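Package: mesoscan
Title: Simulation and Analysis of Dual-Engine Temporally Multiplexed
    Two-Photon Mesoscope Acquisition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator and analysis toolkit for large
    field-of-view two-photon mesoscopes that combine two fully independent
    resonant-galvo-galvo scan engines with temporal multiplexing of the
    excitation pulse trains. Models resonant scan trajectories and timing
    (including the nonuniform pulses-per-pixel profile of a resonant
    sweep), pulse-train interleaving and photon-count demultiplexing with
    fluorescence-lifetime crosstalk, a first-order optical prescription
    with sensorless adaptive-optics optimization, seeded synthetic
    phantoms (bead volumes, calibration line grids, correlated neuron
    fields), point-spread-function measurement pipelines on bead
    z-stacks, and a calcium-trace analysis chain (neuropil subtraction,
    spike deconvolution, distance-binned pairwise correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
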