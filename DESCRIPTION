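Package: markovcea
Title: Markov Cohort Cost-Effectiveness Analysis of Adjuvant Breast-Cancer
    Regimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A half-cycle-corrected, discounted four-state Markov cohort
    model for comparing trastuzumab-containing adjuvant chemotherapy
    strategies in HER2-positive breast cancer.  Derives annual transition
    probabilities from clinical summary statistics (relative risk, median
    overall survival, time to progression and duration of response),
    accumulates discounted costs and quality-adjusted life-years, and
    evaluates incremental cost-effectiveness (ICER, dominance, net
    monetary benefit).  Includes one-way sensitivity analysis with
    tornado ordering, probabilistic sensitivity analysis with
    method-of-moments beta and gamma parameter distributions,
    cost-effectiveness planes and acceptability curves, and a synthetic
    cohort generator with patient-level microsimulation for internal
    model validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
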