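Package: nociguard
Title: Nociceptive Response Index Computation and Simulation of
    Nociception-Guided Anesthesia Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the nociceptive response (NR) index, a logistic
    score of intraoperative nociception built from per-minute heart
    rate, systolic blood pressure and perfusion index, with the
    sampling conventions used in anesthesia information systems
    (1-minute grid, last-observation-carried-forward systolic
    pressure). Provides a synthetic two-arm trial simulator with a
    closed-loop controller emulating NR-guided multimodal anesthesia,
    outcome models linking intraoperative nociception burden to
    postoperative C-reactive protein, Clavien-Dindo complications and
    pain scores, and the full two-arm analysis layer: Wilson score
    intervals, Katz log-method relative risk, uncorrected Pearson
    chi-square, unpaired t and Mann-Whitney U tests, standardized mean
    differences, Bonferroni thresholds, and normal-approximation
    sample-size calculators, plus an end-to-end trial pipeline and a
    simulation-based power harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
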