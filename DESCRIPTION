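Package: tatdose
Title: Preclinical Dosimetry and Efficacy Analysis for Targeted Alpha Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Organ-level absorbed-dose estimation for alpha-emitter-labeled
    radioimmunoconjugates (astatine-211) from mouse biodistribution studies:
    mono- and bi-exponential time-activity-curve fitting, analytic
    time-integrated activity, MIRD-style local-energy-deposition dose with
    branching-ratio-weighted alpha energy, and delta-method or bootstrap
    uncertainties. Companion stages cover Kaplan-Meier survival with
    Mantel-Cox log-rank comparison, hematologic nadir metrics, enzyme
    normal-range flagging, and seeded synthetic-data generators that emulate
    a full preclinical therapy study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
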