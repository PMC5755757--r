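Package: epiforage
Title: Active-Inference Modelling of Epistemic Visual Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative Markov-decision-process model of a gaze-contingent
    scene-categorisation task, with agents that select saccades by expected
    free energy (epistemic plus pragmatic value), inversion of saccadic
    scan-paths to recover subject-level prior beliefs by maximum a posteriori
    estimation with a Laplace approximation, parametric empirical Bayes and
    Bayesian model reduction over between-block effects, Bayesian model
    averaging, and canonical correlation phenotyping of model parameters
    against behavioural performance. Includes a synthetic-cohort generator
    emulating a 22-subject, five-block, hundred-trial study design so that
    every stage of the analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
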