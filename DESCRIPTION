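Package: pazopk
Title: Population Pharmacokinetics of Pazopanib and AUC-Based Exposure Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-compartment population pharmacokinetic model of oral
    pazopanib with first-order absorption, inter-individual and
    inter-occasion variability and an aspartate-transaminase (ASAT)
    covariate on the apparent volume of distribution. Provides SAEM
    (stochastic approximation expectation-maximization) population
    estimation, importance-sampling likelihood, empirical-Bayes (MAP)
    estimation of individual clearance from as little as one sample drawn
    at a random time, conversion of clearance to the area under the
    concentration-time curve (AUC = Dose/(Cl/F)), non-compartmental
    reference AUC (linear-up/log-down), model diagnostics (VPC, NPDE,
    IWRES, bootstrap, leave-one-out cross-validation), and
    sensitivity/specificity determination of a target AUC that acts as a
    surrogate for the trough-concentration efficacy criterion. A synthetic
    cohort generator reproduces the sparse therapeutic-drug-monitoring arm
    and rich-profile trial arm designs so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
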