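Package: ldmrate
Title: Luria-Delbruck Method Estimation of Plasmid Conjugation Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimation of bacterial plasmid conjugation rates from mating
    assays using the Luria-Delbruck Method (LDM), which infers the donor
    conjugation rate from the probability that parallel donor-recipient
    cocultures contain no transconjugants after a short incubation.
    Provides the deterministic mass-action mating model for donors,
    recipients and transconjugants, the analytic transconjugant-free
    probability, an exact Gillespie simulator and a fast hybrid simulator
    of the stochastic assay, the LDM and Simonsen end-point (SIM)
    estimators with volume correction, the classic Luria-Delbruck mutation
    rate estimator, simulation-study machinery (incubation-time and
    parametric-heterogeneity sweeps), and a microtiter-plate layer that
    parses plate records, validates selection controls, converts colony
    counts to densities and generates fully synthetic plate fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
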