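Package: tegt
Title: Evolutionary Game Dynamics on Activity-Driven Temporal Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying n-by-n pairwise evolutionary games in large
    populations whose interaction structure is an activity-driven temporal
    network. Provides the activity-driven network generator with delta-step
    integrated (union) graphs, a fast agent-based Monte Carlo simulator with
    Fermi pairwise imitation and activity-moment observables, the
    weak-selection deterministic theory (transformed payoff matrix
    A' = alpha1*A + alpha2*B built from the original game and its
    antisymmetric local-competition part, replicator-like ODEs, and
    evolutionarily-stable-strategy conditions on temporal networks), the
    activity-moment hierarchy with its slow-manifold reduction, and a full
    analysis of the mini-ultimatum game, where edge temporality promotes the
    evolution of fairness (critical offer threshold, closed-form edge fixed
    points, constant of motion, phase diagram).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
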