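Package: hosprofile
Title: Risk-Adjusted Hospital Outcome Profiling from Administrative and
    Clinical Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds analysis-ready cohorts (acute myocardial infarction
    30-day mortality; hip-fracture surgery within 48 hours) from hospital
    discharge records, drug dispensing registries, admission-level clinical
    variables and a death registry; fits paired risk-adjustment logistic
    models (discharge data only versus discharge data plus clinical
    variables and drug prescriptions) using bootstrap stepwise variable
    selection with forced demographics; and profiles hospitals by direct
    standardisation via a no-intercept centred-covariate logistic model
    with a correction coefficient, funnel-plot control limits and a
    random-intercept sensitivity analysis. Includes a synthetic registry
    generator with known ground truth so the whole pipeline is testable
    without access to confidential regional data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
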