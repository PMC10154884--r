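Package: consdp
Title: Markov Decision Frameworks for Conservation Management Under Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solvers for the family of discrete Markov decision problems that
    arise in conservation and natural-resource management: fully observed
    discounted Markov decision processes (value iteration, backward
    induction), adaptive management under structural uncertainty (active and
    passive optimization over a Bayesian model state on a simplex grid),
    partially observable processes (exact finite-horizon alpha-vector backup
    and point-based approximation), mixed-observability processes with
    jointly observable and hidden state components, and nonstationary
    hidden-model dynamics in which the governing model drifts by a Markov
    chain.  Includes brute-force oracles (stationary-policy enumeration,
    expectimax belief trees, joint-distribution filters), Monte-Carlo policy
    rollouts, seeded synthetic problem generators including a toy wildlife
    harvest family, a label-keyed JSON problem-file format, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
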