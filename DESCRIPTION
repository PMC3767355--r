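Package: macroconf
Title: Conformational Analysis of 18-Membered Alpha,Beta-Unsaturated Macrolactones
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds 18-membered alpha,beta-unsaturated macrolactone models
    (a symmetric and a dissymmetric isomer, with or without a
    tricarbonyliron steric model bound to the diene), samples their
    conformers by Metropolis Monte Carlo in ring-torsion space over a
    simplified Allinger-style molecular-mechanics energy with quench
    minimisation, classifies each conformer into one of eight geometric
    types from the diene torsion, the enone ester torsion and the mutual
    arrangement of the two site planes, and converts per-type relative
    energies into Boltzmann populations at a calibrated effective
    temperature. Includes multi-conformer XYZ and SDF V2000 input/output
    and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ChemmineR
Config/testthat/edition: 3
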