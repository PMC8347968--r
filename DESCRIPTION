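Package: basalloop
Title: Dynamic Basal Insulin Needs Estimation in Closed-Loop Glucose Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a patient's basal insulin needs on-line from continuous
    glucose monitor (CGM) readings and the dose history, by decomposing past
    insulin into instantaneous boluses (iIOB) and regressing the glucose
    derivative on instantaneous insulin with a fixed, pre-configured insulin
    sensitivity factor. The estimator is embedded in a single-hormone
    closed-loop controller with trend-safe basal finalization, adaptive
    insulin sensitivity, a dynamic glycemic target and a low-threshold
    suspend. A self-contained minimal-model virtual patient (glucose-insulin
    kinetics, gut absorption, CGM delay and autocorrelated noise, infusion
    blockage) supports desk-scale in-silico experiments: fasting, meals,
    partial infusion blockage and their combination, with time-in-range and
    total-daily-dose reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
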