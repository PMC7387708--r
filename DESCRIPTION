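Package: skilltrackr
Title: Latent Working-Memory Skill Tracking for Adaptive N-Back Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates a participant's latent working-memory skill from
    adaptive N-back training logs. Implements an input-output hidden Markov
    model with four-parameter logistic item-response emissions and
    beta-binomial overdispersion, trained by Baum-Welch
    expectation-maximization with tied structured transition parameters; an
    unscented Kalman filter alternative with EM parameter estimation; a small
    LSTM sequence-regression baseline written in base R; a simulator of the
    adaptive staircase, mini-block and blockwise progression algorithms used
    in N-back training studies, for generating synthetic cohorts with known
    ground-truth skill; and an evaluation harness based on one-step-ahead
    block-accuracy prediction error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
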