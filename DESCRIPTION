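Package: colonsim
Title: Agent-Based Metabolic Simulation of a Colon-Like Environment
Version: 0.1.0
Authors@R: person("colonsim", "developers", role = c("aut", "cre"),
    email = "colonsim@example.org")
Description: A spatiotemporal, agent-based simulator of host-microbiome
    metabolic interactions in a two-dimensional colon-like arena with
    crypts, a two-layer mucus barrier, sectored diffusion and luminal
    flow. Each bacterial or host cell is an agent whose metabolism is
    solved by parsimonious flux balance analysis at every time step.
    Includes a self-contained linear/mixed-integer programming core
    (FBA, pFBA, shadow prices, iMAT-style context-specific model
    extraction), SBML/JSON model input-output with diet and basolateral
    compartment surgery, a toy-community generator so every stage is
    testable without genome-scale downloads, and downstream analytics
    of cross-feeding (net-flux summaries, producer-consumer tables,
    interaction-frequency filtering, growth rates by mucosal layer).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
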