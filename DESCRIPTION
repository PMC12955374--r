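Package: pestwas
Title: Duration-Based Pesticide-Wide Association Scans with
    Distributed-Lag Window Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for record-based ambient pesticide exposure assessment and
    pesticide-wide association scans in case-control studies of Parkinson's
    disease. Builds annual proximity exposures from application records and
    address histories using a fixed-radius buffer, derives proportion-of-years
    duration metrics with a prodromal lag, runs per-pesticide covariate-adjusted
    logistic models with fixed-effect meta-analysis across exposure locations
    and false discovery rate control, fits constrained distributed-lag models
    over decade-long pre-diagnostic windows with a natural cubic spline
    lag-response and a null first lag period, and compares duration-based with
    intensity-based effect estimates (ratio of odds ratios, paired t-test,
    Bland-Altman limits of agreement). Includes a synthetic-data generator that
    emulates multi-decade pesticide use reporting records, address histories,
    and case-control outcomes with known planted effects, so the full pipeline
    is testable end to end without access to confidential study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    splines,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
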