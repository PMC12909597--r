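Package: linegate
Title: Treatment-Time Prediction for Respiratory-Gated Line-Scanning Proton
    Therapy under Dynamic-Range Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models how the dynamic-range constraint (the permitted ratio of
    maximum to minimum monitor units within an energy layer) changes layer
    dose rates and beam-on times in line-scanning proton therapy, and
    simulates layer-by-layer delivery under amplitude-based respiratory
    gating to predict total treatment time. Includes a seeded synthetic plan
    generator, a three-component sinusoidal breathing model with
    duty-cycle-calibrated gating thresholds, an event-driven delivery
    simulator with an independent time-stepping oracle, and a dynamic-range
    sweep with plateau detection so planners can find the patient-specific
    threshold below which further dynamic-range reduction gains nothing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
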