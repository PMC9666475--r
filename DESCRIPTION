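Package: nestnet
Title: Socio-Spatial Network Analysis and Movement Simulation for Social
    Insect Nests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing within-nest trajectories of individually
    tracked social-insect workers. Trajectories are discretised onto a
    hexagonal lattice and summarised as a weighted bipartite worker-by-site
    visit network, which is partitioned into spatial modules by a stochastic
    weighted bipartite label-propagation algorithm (Barber modularity).
    Repeated partitioning yields fuzzy per-node module scores that support
    entropy-based mixing indices, worker-site cosine similarity, taxis
    indices toward module boundaries, module-score gradient fields, and
    gradient-relative turning statistics. A correlated-random-walk agent
    simulator with three pluggable movement mechanisms (focal-point
    attraction, locomotion adjustment, boundary effect) generates synthetic
    colonies with planted ground truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
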