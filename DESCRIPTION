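Package: atheromod
Title: Mechanistic Stochastic Modelling of Atherosclerosis and Stroke in
    Occupational Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A stochastic multi-stage model of atherosclerosis for use in
    cohort epidemiology.  Monocytes enter the arterial wall and become
    macrophages, macrophages proliferate and turn into foam cells, and foam
    cells seed vulnerable plaques that cause stroke after a fixed lag.  The
    package provides an exact Monte-Carlo simulator of the cell-count
    process, an analytic survival and hazard solver based on backward
    Kolmogorov equations for independent cell lineages, individual-likelihood
    fitting of the mechanistic model and of an empirical log-linear baseline
    model to occupational cohort data with age power laws, categorical
    covariate modifiers and radiation dose response, profile-likelihood
    confidence intervals and likelihood-ratio tests, and a synthetic cohort
    generator with recorded generating truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
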