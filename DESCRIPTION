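Package: oncoburden
Title: Desk-Scale Cancer Burden Estimation Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained, desk-scale implementation of a multi-stage
    cancer burden estimation pipeline: a synthetic registry/vital-registration
    world generator with known ground truth, ICD cause mapping and garbage-code
    redistribution, three-stage space-time Gaussian process smoothing of
    mortality-to-incidence ratios (MIRs), an out-of-sample-weighted ensemble of
    mortality submodels scaled to an all-cause envelope, MIR-based incidence
    back-calculation, survival-based 10-year prevalence and sequela YLDs, and
    final burden metrics (YLLs, DALYs, age-standardized rates, annualized rates
    of change, uncertainty intervals, and Sociodemographic Index quintiles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Matrix,
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
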