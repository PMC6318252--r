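Package: poppet
Title: Protection Factor Prediction for Hydrogen-Deuterium Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-residue protection factors (PFs) of backbone amide
    hydrogens from protein structural features and HX-enabling motion
    annotations via the POPPeT log-linear model, fitted by ordinary least
    squares with backward elimination. Implements the competing predictors
    commonly benchmarked against it (the phenomenological approximation from
    hydrogen-bond and burial counts, and COREX-style Boltzmann aggregation
    over partially unfolded microstates), computes intrinsic amide exchange
    rates from the Bai reference parameterization, and propagates protection
    factors into theoretical residue- and peptide-level deuterium-uptake
    curves so that prediction error can be quantified on the deuteration
    scale. Includes structural feature extraction (burial, secondary
    structure, geometric hydrogen bonding) from PDB files and deterministic
    synthetic fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
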