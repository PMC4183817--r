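Package: sahspring
Title: Single-Molecule Force Spectroscopy of Single Alpha-Helix Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to simulate and analyse atomic force microscopy (AFM)
    pulling experiments on polyprotein constructs containing single
    alpha-helix (SAH) domains. Provides wormlike-chain and helix-coil
    mechanical element models, a stochastic constant-velocity pulling
    simulator with Bell-model unfolding kinetics, the full sawtooth-trace
    analysis pipeline (peak detection, trace selection, global and
    first-peak wormlike-chain fits, peak-to-peak distances, trace
    alignment and force-extension density maps), circular dichroism
    helicity computations, and coordinate-based structure metrics
    (end-to-end distance, distance-matrix RMSD, helicity assignment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
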