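Package: wearhr
Title: Free-Living Validation of Wearable Heart-Rate Monitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for validating wrist-worn optical heart-rate trackers
    against a chest-strap reference under free-living conditions. Aligns a
    1-min tracker stream with a 10-s reference stream into common-wear
    clock-minute epochs, classifies age-based heart-rate zones (moderate to
    vigorous physical activity at >= 50% of age-predicted maximal heart
    rate), and computes method-agreement statistics: two-way absolute
    agreement intraclass correlation ICC(A,1) with F-based confidence
    intervals, paired mean bias, and Bland-Altman limits of agreement.
    Includes 2x2 MVPA-detection diagnostics (sensitivity, specificity,
    predictive values), wear-time and valid-day compliance summaries, and a
    seeded synthetic cohort generator producing paired free-living streams
    with participant-specific intensity-dependent device error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
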