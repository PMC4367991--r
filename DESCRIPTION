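Package: groupgames
Title: Evolutionary Game Dynamics of Small Groups with Heterogeneous
    Preferences on a Lattice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of behavioral evolution in a population
    composed of two fixed-membership small groups placed on a periodic square
    lattice. Each group prefers one of two behaviors through an internal
    harmony game while cross-group encounters follow a different 2x2 game
    (typically a snowdrift game). The package provides exact game-theoretic
    algebra (payoff-matrix simplification, dilemma classification, pure Nash
    equilibrium enumeration, and the relative-degree-of-preference statistic
    q), a fast synchronous best-neighbor imitation simulator, the
    convergence-and-averaging measurement protocol, replicated parameter
    sweeps over the group-1 fraction f and the cohesion ratio q, lattice
    snapshot export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
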