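Package: promcm
Title: Markov-Chain Models of Gene Induction by Competing Transcription
    Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete-time Markov-chain models of promoter-state switching
    for a gene regulated by a doxycycline-controlled activator and repressor
    that bind the same site in a mutually exclusive manner.  Switching
    probabilities are Hill functions of inducer concentration estimated from
    activator-only and repressor-only dose-response curves under a
    binding-contingency penalty; single-cell expression is simulated with a
    telegraph-driven birth-death solver with noisy degradation and basal
    leakage; population dose-response curves are refitted with Hill
    functions to predict the cooperativity (Hill coefficient) of the
    combined activator-plus-repressor system and to classify graded versus
    all-or-none expression distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
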