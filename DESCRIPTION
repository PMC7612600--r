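Package: umbrellasim
Title: Simulation of Treatment Allocation Strategies for Biomarker-Guided
    Umbrella Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates phase II umbrella trials in which patients may test
    positive for several of the biomarkers that define the treatment arms,
    so that multi-positive (and all-negative) patients are eligible for more
    than one experimental treatment.  Implements five allocation strategies
    for such patients (equal randomisation, randomisation with a fixed
    control probability, a pre-specified biomarker hierarchy, constrained
    randomisation towards under-accrued arms, and Bayesian adaptive
    randomisation with interim posterior updates), a logistic outcome model
    with treatment-biomarker interactions, one-sided Wald tests of the
    treatment-in-subgroup hypotheses, and Monte-Carlo estimation of
    operating characteristics: power, type I error, allocation proportions,
    proportion of patients on their best available treatment, and bias/MSE
    of the subgroup effect estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
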