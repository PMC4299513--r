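Package: growthlaws
Title: Coarse-Grained Proteome Allocation Model of Bacterial Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses a coarse-grained flux-balance model of
    bacterial growth in which the proteome is partitioned into ribosomal and
    metabolic sectors. Provides sigmoidal rate laws for translational and
    nutritional efficiency, steady-state flux-balance solvers, growth-rate
    optimization over the ribosomal protein fraction, a two-variable
    dynamical system for supply-driven activation of ribosome synthesis with
    stability analysis, emergent growth-law sweeps and fitting, Monod
    kinetics for substrate-limited growth, and mass-fraction/concentration
    unit conversions. Includes a synthetic-data generator for noisy growth
    tables and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
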