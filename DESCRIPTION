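Package: emsadp
Title: Two-Tiered Ambulance Dispatch and Redeployment with Monotone
    Approximate Dynamic Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-event semi-Markov decision process simulator for
    two-tiered (ALS/BLS) emergency medical service systems with patient
    severity classification errors, a risk-level-index (RLI) objective,
    greedy and myopic dispatch baselines, and a mini-batch monotone
    approximate dynamic programming (ADP) learner over an aggregated
    spatio-temporal state space. Includes common-random-number paired
    policy comparison, full-factorial experiments over fleet composition
    and triage error rates, and operational dispatch indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
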