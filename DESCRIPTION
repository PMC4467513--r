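Package: vacause
Title: Hierarchical Cause-of-Death Assignment for Child Verbal Autopsy Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assigns causes of death to under-five verbal autopsy (VA)
    records with a standardized, age-stratified hierarchy of symptom-based
    case definitions. Case definitions are declarative boolean predicate
    trees over coded questionnaire items (with duration windows and count
    thresholds) and are shipped as editable configuration. Deaths matching
    the measles/diarrhea/acute-respiratory-infection group can be assigned
    jointly and are redistributed in proportion to pre-redistribution
    cause-specific mortality fractions (CSMFs). Includes survey-weighted
    CSMF estimation with Taylor-linearized standard errors, CHERG-style
    cause grouping, top-k cause ranking, per-cause Cohen's kappa against a
    second coder, and a truth-known synthetic VA data generator for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
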