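Package: refbackddm
Title: Diffusion Decision Modeling of Reference-Back Working-Memory Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for model-based analysis of cognitive control in working
    memory with the reference-back task. Implements the full diffusion decision
    model (Wiener first-passage-time density with drift and start-point
    variability), reference-back trial annotation and factorial model variants,
    synthetic data generation from hierarchical group models, per-subject and
    hierarchical Bayesian estimation by differential-evolution MCMC, DIC model
    selection, posterior inference on the six canonical reference-back cost
    contrasts, posterior predictive checks, and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
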