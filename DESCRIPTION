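Package: consensusbn
Title: Consensus Bayesian Networks for Regulatory Pathway Modelling
Version: 0.1.0
Authors@R: person("ConsensusBN", "Developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Learns discrete Bayesian networks from (discretized expression)
    data with an information-theoretic three-phase algorithm, and combines
    two or more networks -- possibly defined over different variable sets --
    into a single consensus network via conditional probability table
    extension, weighted aggregation, and variance-based simplification.
    Includes exact inference by variable elimination, forward sampling,
    a mutual-information based associated-gene prediction program, tertile
    (q3) discretization of expression matrices, a split/merge validation
    harness, and plain-text network interchange including a BIF reader.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
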