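Package: sedverify
Title: Lint, Repair, and Cross-Engine Verification of Simulation Experiment Archives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for making simulation-experiment archives verifiable.
    Reads and writes COMBINE/OMEX archives bundling SBML kinetic models with
    SED-ML experiment descriptions, detects and repairs a catalogue of archive
    and experiment defects (dangling model sources, broken element pointers,
    unused or duplicated elements, inconsistent simulation settings, non-finite
    parameters, annotation URN forms), generates template time-course
    experiments for models lacking one, executes experiments on two independent
    ODE backends (an adaptive Dormand-Prince 4(5) integrator and a BDF
    multistep integrator) with per-variable absolute-tolerance scaling, and
    declares cross-engine replication using an element-wise tolerance
    criterion with a match score, pairwise aggregation, and reproducibility
    level classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    deSolve,
    yaml,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
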