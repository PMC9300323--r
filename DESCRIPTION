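Package: midecode
Title: Motor-Imagery EEG Decoding with CSP and Fisher LDA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-class motor-imagery EEG decoding:
    subject-specific frequency-band selection via the signed r-squared
    (point-biserial) discriminability spectrum, zero-phase band-pass
    filtering, Common Spatial Patterns (CSP) spatial filtering with
    normalized-variance features, and closed-form Fisher linear discriminant
    classification, evaluated with leakage-free stratified cross-validation.
    Includes a synthetic generator of event-related-desynchronization (ERD)
    motor-imagery EEG with a known linear forward model, EDF and CSV trial
    readers/writers, and a study-statistics stage (per-condition summaries,
    one-way repeated-measures ANOVA, exploratory paired comparisons) for a
    subjects-by-conditions accuracy table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
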