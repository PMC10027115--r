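Package: cellcalib
Title: Black-Box Calibration of Agent-Based Cell Simulations by Multilevel Grid Sweeps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates parameters of agent-based cell simulators against target
    data without access to model internals. Reads, validates and edits
    PhysiCell-style XML settings files with typed numeric constraints, wraps any
    simulator executable (or in-process function) as a black-box map from
    parameter values to an output metric with replicate execution, reduces
    simulation snapshots (cell positions, counts) to metric vectors, and fits
    two parameters by a multilevel grid search that recenters and shrinks the
    search range around the best point at each level, minimizing the summed
    squared error against the target. Ships self-contained fixture models
    (logistic growth, a biased persistent random walk chemotaxis model) so the
    whole pipeline runs and is testable without an external simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
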