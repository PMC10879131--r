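Package: washeq
Title: Equity and Seasonal Effect Modification of WASH Interventions on
    Child Diarrhea, with Gridded Burden Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse how a combined water, sanitation and
    handwashing (WASH) intervention modifies child-diarrhea risk along an
    asset-based wealth gradient and across monsoon and dry seasons, and to
    extrapolate trial effects to gridded rural populations.  Implements an
    asset-based wealth index by principal components with screening,
    imputation, ranking and tertile rules; monsoon-season classification
    from daily precipitation by a rolling-mean threshold; the Relative and
    Slope Indices of Inequality from log-link binomial regression on wealth
    rank with block-clustered sandwich errors; stratum-level prevalence
    differences and ratios with Wald-type F interaction tests; penalized
    cubic regression spline (GAM, REML) dose-response curves over wealth
    rank with block random effects; and projection of prevented diarrhea
    cases onto population rasters with delta-method district uncertainty.
    Includes a seeded synthetic-data generator that emulates the trial
    design (matched blocks, cluster randomization, wealth- and
    season-graded risk) and raster fixtures so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    sandwich,
    zoo,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
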