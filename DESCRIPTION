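Package: fairdg
Title: Inequity-Aversion Modelling of Gain- and Loss-Framed Dictator Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, model-free analysis and hierarchical Bayesian
    modelling of allocation choices in a modified dictator game in which
    participants allocate tokens for themselves (first-party) or on behalf
    of another dictator (third-party), under gain and loss framing and
    varying exchange ratios. Provides the task arithmetic (choice sets,
    payoff conversion, selfish and equal reference rules), a synthetic-data
    generator with ground-truth Fehr-Schmidt parameters, mixed-design
    ANOVA on behavioral deviation scores, five competing inequity-aversion
    utility models with a softmax choice rule, hierarchical Bayesian
    estimation by adaptive Markov chain Monte Carlo, WAIC and PSIS-LOO
    model comparison, posterior predictive checks, and highest-density
    interval evidence summaries for condition and group contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
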