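Package: wirenet
Title: Structural Analysis of Neuronal Wiring Diagrams
Version: 0.1.0
Authors@R: person("Wiring", "Analyst", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the structural analysis of neuronal wiring diagrams
    such as the C. elegans connectome: loading and validating neuron and
    synapse tables, building gap-junction and chemical-synapse adjacency
    networks, degree/multiplicity/terminal statistics with maximum-likelihood
    tail fitting (discrete power law, exponential, stretched exponential),
    giant-component analytics from generating functions, small-world and
    closeness-centrality measures against degree-matched rewiring null
    models, motif censuses with constrained null ensembles and step-down
    min-P multiple-testing correction, linear (resistive/tonic-release)
    dynamics on the weighted network with eigenmode and pseudospectrum
    analysis, spectral signal-flow and affinity layouts, gap-chemical
    interaction statistics, a synthetic connectome generator, and a
    robustness-to-reconstruction-error analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
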