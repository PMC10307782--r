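Package: tppunish
Title: Computational Models of Social-Distance-Modulated Third-Party Punishment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling third-party punishment choices in the
    modified Third-Party Dictator Game, where an observer may pay to reduce
    the payoff of a dictator at a given social distance. Implements the
    third-party inequity-aversion utility model, four social-distance
    transforms (hyperbolic discounting and flexible power functions applied
    to either the punishment level or the inequity-aversion weight), a
    softmax discrete-choice likelihood, per-subject penalized maximum
    likelihood estimation with Laplace or BIC approximations to the log
    model evidence, and random-effects Bayesian model selection with
    exceedance probabilities, Bayesian omnibus risk and protected
    exceedance probabilities. A synthetic-data generator reproduces the
    task design (8 social distances, 3 unfair allocations, costly and free
    punishment conditions, 6 sessions of 54 trials) so parameter- and
    model-recovery studies run without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
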