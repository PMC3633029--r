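Package: gcfounders
Title: Estimating Germinal Center Founder-Cell Diversity from Immunohistological Sections
Version: 0.1.0
Authors@R:
    person("gcfounders", "authors", email = "gcfounders@example.org",
           role = c("aut", "cre"))
Description: Probabilistic models for estimating the clonal diversity of
    germinal centers (GCs) from immunohistological sections of two-phenotype
    chimeric animals. Implements the basic binomial seeding model, an extended
    model with hypergeometric section sampling, scoring-error thresholds and
    Poisson-distributed founder numbers fitted by chi-square grid search,
    Yule-Simon and ACE richness estimators for clone-abundance samples, a
    Monte-Carlo forward simulator that validates the analytic probabilities,
    and a synthetic stained-section renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
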