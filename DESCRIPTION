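Package: kfsdmi
Title: Dry Matter Intake Prediction and Evaluation for Lactating Dairy Cows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the Korean feeding standards for dairy cattle (KFSD)
    empirical dry-matter-intake (DMI) prediction equation for lactating
    Holstein cows together with the machinery needed to develop, evaluate and
    stress-test such equations: comparator equations (NRC 2001, CNCPS, the
    Japanese feeding standard) with early-lactation lag multipliers; a
    literature-database filtering pipeline with development/evaluation
    splitting; two-phase model development (study-random coefficient models
    with AIC/BIC all-subsets selection, then ordinary least squares);
    evaluation statistics (RMSPE, observed-on-predicted regression, mean and
    slope bias from residual regression); Latin-hypercube sensitivity
    analysis with standardized regression coefficients; and seeded synthetic
    generators for study-clustered literature treatment means and monthly
    farm-trial records with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lhs,
    fitdistrplus,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
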