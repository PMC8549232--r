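Package: lemocot
Title: Automated Analysis of the Lower-Extremity Motor Coordination Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to score the lower-extremity motor coordination test
    (LEMOCOT) from pressure-mat force recordings. Detects individual toe
    touches in a 60 Hz force-sensor grid time series, classifies them into
    proximal-target, distal-target and between-target zones, computes the
    traditional in-target count together with refined motor-performance
    parameters (contact surface, endpoint and centre-of-pressure locations,
    absolute and variable error, endpoint-COP distance), and provides the
    accompanying statistical layer: count validation against a manual
    tester with a random-intercept mixed model and conditional pseudo
    R-squared, speed-accuracy residualization against a control-group
    model, group-by-leg mixed models with Holm-adjusted post hocs, and
    Spearman associations with clinical scores. A seeded simulator
    generates synthetic recordings with full ground truth so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
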