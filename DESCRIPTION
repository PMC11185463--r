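Package: rookery
Title: Nesting-Season Phenology and Rookery Abundance from Sparse Beach Surveys
Version: 0.1.0
Authors@R:
    person("GLS", "Monitoring", email = "gls.monitoring@example.org",
           role = c("aut", "cre"))
Description: Estimates seasonal and multi-season sea-turtle nesting abundance
    from sparse repeated beach-survey counts on many small islets. Fits a
    piecewise-cosine nesting-season curve by maximum likelihood with
    detection-aware (censored) Poisson or negative-binomial window
    likelihoods, models nest-track persistence from repeated observations of
    marked nests (logistic decay with within-track AR1 dependence), imputes
    unmonitored islet-seasons from sum-to-one site proportions under a gamma
    observation model, and produces Bayesian seasonal and multi-season nest
    totals with credible intervals via adaptive Metropolis-Hastings. Includes
    a synthetic-rookery generator with known ground truth and a command-line
    pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS,
    nlme,
    withr
Config/testthat/edition: 3
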