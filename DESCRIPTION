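Package: scmforage
Title: Sequential Choice Model Simulation and Analysis for Context-Dependent Foraging
Version: 0.1.0
Authors@R:
    person("scmforage", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse operant foraging experiments in
    which animals learn option values in separate contexts and occasionally
    face simultaneous choices. Implements a two-context session scheduler
    with reward-rate equalisation of inter-trial intervals, a generator of
    context- and immediacy-dependent response latencies with a reaction-time
    floor, peak-interval timing curves, and the Sequential Choice Model: a
    race between independently drawn latencies that predicts simultaneous
    choice preference and censored choice-latency distributions from
    no-choice latencies, via Monte Carlo resampling or analytic quadrature.
    Includes latency analytics (empirical-CDF area scores, shortening
    comparisons, stability criteria, tests against indifference) and an
    end-to-end pipeline reproducing the full design at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
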