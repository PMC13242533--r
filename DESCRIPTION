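Package: surgdelay
Title: Health Effects of Alternative Treatments During Surgical Delay
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A three-state cohort state-transition model (alternative
    treatment, surgery, deceased) that estimates the health loss, in
    disability-adjusted life-years (DALYs) per month of surgical delay, of
    temporarily substituting a surgery with a nonsurgical alternative
    treatment. Ships a registry of disease-surgery-alternative parameter
    sets (survival probabilities, utilities, ages, hazard-ratio treatment
    effects), converts horizon survival probabilities to constant hazards,
    imputes missing survival arms under proportional hazards, runs a
    seeded probabilistic sensitivity analysis with beta, triangular,
    normal and lognormal parameter distributions, and ranks
    disease-surgery pairs by the DALYs of their best alternative as a
    surgical prioritization aid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
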