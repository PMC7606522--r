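Package: heatgrowth
Title: Temperature Exposure and Child Anthropometry: Fixed-Effects
    Estimation and Climate Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the effect of ambient temperature on child
    nutrition outcomes from georeferenced survey data. Implements WHO-style
    LMS anthropometric Z-scoring with quality-control flagging, multi-scale
    nonlinear temperature exposure construction (binned monthly counts,
    degree-months, polynomial terms) over survey-month, prior-year, lifetime,
    trimester and crop growing-season windows, survey-weighted least squares
    with high-dimensional fixed-effect absorption and cluster-robust
    inference, crop-area-weighted regressions, temperature response curves
    with delta-method intervals, and distribution-shifting projections of
    future wasting prevalence with parameter-uncertainty bands. Ships a
    synthetic-data module that generates DHS-like cohorts, gridded monthly
    climate, crop maps and warming scenarios with known injected responses so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
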