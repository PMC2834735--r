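Package: bactaxis
Title: Frequency-Domain Design and Agent-Based Evaluation of Bacterial
    Chemotaxis Pathways
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reverse engineering bacterial chemotaxis signalling:
    pathway ODE models (designed three-molecule positive/negative/pseudo
    pathways and a universal activation/deactivation network), equilibrium
    finding and linearization into rational transfer functions, Bode
    (frequency-domain) analysis and filter classification, canonical low-pass
    and band-pass controller filters with exact zero-order-hold time stepping
    and step-response timing, a CheY-P-driven two-state flagellar motor model,
    static 2-D ligand concentration fields, a run-and-tumble agent-based
    population simulator, and chemotactic-effect statistics with parameter
    scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
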