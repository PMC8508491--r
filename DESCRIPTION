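Package: itemtwo
Title: Gas-Phase Dissociation Analysis of Non-Covalent Complexes from
    Stepped Collision-Voltage Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ITEM-TWO style analysis of native electrospray
    mass spectra of non-covalent protein-peptide complexes. Reads
    centroided peak lists recorded at stepped collision-cell voltage
    differences, fits Gaussian charge-state envelopes, builds normalized
    educt survival curves, fits Boltzmann sigmoids, and derives apparent
    gas-phase kinetic and thermodynamic quantities (rate constant,
    equilibrium dissociation constant, Gibbs energy, enthalpy and entropy
    terms) via Arrhenius and van't Hoff analysis evaluated at ambient
    temperature. Also provides a Monte-Carlo sampler of protonation
    patterns over basic sites scored by Coulomb energy with the
    multiple-run-multiple-states-Arg (MMSA) selection rule, inter-chain
    atom-contact statistics ("position-to-sum" ratios) over multi-model
    structure ensembles, and synthetic-data generators with known ground
    truth for every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
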