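Package: tempbias
Title: Simulating Temporal Bias in Case-Control Study Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation machinery for quantifying temporal bias: the
    distortion that arises when case observations are indexed to a future
    event. Provides synthetic cohort generators (biomarker centile tables,
    claims-like coded event streams, longitudinal yearly exposures, repeated
    biomarker measurements), control-to-case trajectory models with
    start-value imputation, a prospective-effect pipeline that measures
    attenuation of case-control effect sizes under uniform-in-time sampling,
    a study-design harness contrasting event-indexed and calendar-fixed
    observation windows, a measurement-selection analysis, and a
    lookback-window sensitivity sweep with false-discovery-rate control.
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
    jsonlite,
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
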