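Package: tsgc
Title: Comparing Groups of Time Series with Mixed Models and ARIMA Whitening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage comparison of groups of densely sampled time series,
    as used for longitudinal plant-phenotyping data such as chlorophyll
    fluorescence during de-etiolation. A linear mixed model captures the
    common quadratic trend with subject-specific random intercept, slope and
    curvature under an unstructured covariance; per-subject ARIMA models
    absorb the autocorrelation remaining in the mixed-model residuals; and
    per-timepoint two-sample t-tests with Bonferroni correction across group
    pairs yield contiguous significance windows in minutes. Includes
    autocorrelation and KPSS stationarity diagnostics, an automated stepwise
    AICc order search for the residual ARIMA models, a synthetic panel
    generator with known ground truth for operating-characteristic studies,
    and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
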