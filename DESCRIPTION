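Package: queds
Title: Formal Psychological Assessment Engine for the QuEDS Depression Instrument
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the QuEDS (Qualitative-quantitative Evaluation of
    Depressive Symptomatology) major-depressive-episode questionnaire and the
    Formal Psychological Assessment machinery behind it: the items-by-criteria
    Boolean clinical context, Galois derivation operators and formal concepts,
    the prerequisite (surmise) relation, the delineated clinical structure
    under the conjunctive attribution model, and a deterministic half-split
    adaptive administration procedure.  A psychometric validation battery
    (KR-20/Cronbach alpha, test-retest, known-groups t and ROC analysis,
    dependent and independent correlation comparisons) and a calibrated
    hierarchical-factor synthetic-respondent generator allow every stage of
    the validation pipeline to be exercised without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
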