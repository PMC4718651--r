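Package: socialcascade
Title: Bayesian Analysis of Social Influence in Sequential Decision Making
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying information cascades in sequential binary
    decision tasks. Implements the normative Bayesian observer that infers
    predecessors' private signals from their public decisions and integrates
    them on the log-odds scale; a social influence model that weights private,
    peer, and authority-derived evidence differentially and maps subjective
    posteriors to choice probabilities through a sensitivity parameter;
    synthetic participant cohorts with known parameters; per-participant
    Markov chain Monte Carlo estimation with truncated-normal and uniform
    priors, chain pooling, and highest density interval summaries; and a
    reporting layer with scenario-group choice aggregates, authority
    contrasts, and observed-versus-predicted probability judgment comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
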