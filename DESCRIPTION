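Package: darchsim
Title: Data-Driven Simulation of Protein Domain Architecture Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation of protein domain architecture evolution.
    Domain architectures (ordered lists of domain superfamily tokens) evolve
    by single-domain gains and losses under a Metropolis-Hastings chain whose
    acceptance probabilities derive from a first-order (bigram) model with
    add-k smoothing trained on genuine genome annotations. Includes the
    training pipeline (annotation parsing, architecture assembly,
    deduplication, n-gram counting), convergence diagnostics (Gelman-Rubin
    shrink factor, acceptance-rate tracking), an evaluation battery comparing
    simulated and genuine architecture sets (n-gram frequencies, pair
    co-occurrence, domain promiscuity, tandem-array statistics, probability
    quantile comparison, event-position histograms), and a synthetic-corpus
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, jsonlite, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
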