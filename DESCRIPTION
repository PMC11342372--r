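Package: clusterEA
Title: Dynamic Cluster-Selection Evolutionary Algorithm for Molecular
    Structure Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global-minimum molecular structure search by a cut-and-splice
    evolutionary algorithm whose effort is allocated across structurally
    defined clusters by a four-parameter reinforcement-learning agent.
    Provides radial-distribution structure fingerprints with cosine
    distances, complete-linkage agglomerative clustering with misfit-pool
    consolidation, the weighted bandit-style cluster-selection agent, a
    Gaussian surrogate simulator and grid search for tuning the agent's
    learning parameters, clustered and unclustered EA drivers with
    energy-threshold parent curation, a synthetic atom-by-atom structure
    builder, and a pluggable energy-calculator contract with a toy Morse
    potential for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
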