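Package: kinsteer
Title: Uncertainty-Aware Kinetics-Steered Exploration of Chemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Microkinetic modeling of chemical reaction networks with
    mass-action kinetics and Eyring transition-state-theory rate constants,
    combined with local one-at-a-time (OAT) and Morris elementary-effects
    sensitivity analysis over free-energy parameters.  Sensitivity results
    steer both which species to explore next (classic and uncertainty-aware
    selection criteria) and which kinetic parameters to refine through a
    ladder of energy-model fidelity ranks.  Quantum-chemistry backends are
    replaced by a pluggable multi-fidelity energy oracle; a synthetic
    network generator with calibrated cross-rank error statistics, a
    shortest-path extractor with compound costs, and serialization to a
    structured-text network schema and SBML complete the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
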