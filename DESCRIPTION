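Package: tpgsim
Title: Temporal Partitioning Congestion Game Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of temporal partitioning congestion
    games: populations of heterogeneous agents repeatedly choose when to
    use a shared resource whose per-slot capacity is limited, so that
    crowding imposes a purely pecuniary externality.  Implements the
    'blossom game' (visitors choosing a day of a short flowering season)
    under a 2x2 design crossing information (local versus global
    knowledge of past attendance) with multiplicative exploration-decay
    learning, a population-turnover scenario, a typed variant modelling
    bats partitioning nightly waterhole visits with same-type affinity,
    and a static Nash-equilibrium toolkit (verification, greedy
    construction of preference-ordered equilibria, and exhaustive
    enumeration on small instances).  Runs are fully seeded and emit
    per-season records, convergence diagnostics, and CSV/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
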