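Package: cthmmprog
Title: Continuous-Time Hidden Markov Models for Disease Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits continuous-time hidden Markov models (CTHMMs) to
    irregularly sampled longitudinal cohort data, for staging slowly
    progressing chronic diseases. The hidden disease state evolves as a
    continuous-time Markov chain with a structurally constrained transition
    generator (full, forward, or order-L forward-chain, with optional
    absorbing terminal state); observed clinical features follow independent
    Gaussian emissions per state. Estimation is by soft
    expectation-maximization with endpoint-conditioned expected transition
    counts and sojourn times computed through auxiliary block-matrix
    exponentials. Includes held-out log-likelihood selection of the number
    of states, Viterbi decoding of individual state sequences, forward
    prediction of states and features, expected state durations, a cohort
    simulator for validation, delimited-text readers and writers, JSON
    model serialization, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
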