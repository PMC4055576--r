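Package: multicontagion
Title: Concurrent Spread of Multiple Contagions on Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Discrete-time stochastic modelling of an arbitrary number of
    concurrently spreading contagions on arbitrary and multiplex networks.
    Implements the synchronous reactive process with spontaneous and
    contact-induced state changes, the exact multi-transmission adoption
    probability together with a tractable closed-form approximation, the
    deterministic (expected-value) discrete-time solver with exact and
    approximate backends, continuous-time rate equations with fixed-step
    integration, and preset reductions to the SIS, SIR, SIRS, Maki-Thompson
    and two-contagion competition models, including their multiplex variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    deSolve,
    pracma,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
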