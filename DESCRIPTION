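Package: glycman
Title: Medication-Adjusted Glycaemic Outcomes for Type 2 Diabetes Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring and analysis machinery for randomised trials of
    glucose-lowering interventions in type 2 diabetes under routine primary
    care. Implements the medication effect score (MES) for quantifying
    glucose-lowering drug regimens, MES-corrected HbA1c, a composite
    "glycaemic management" categorical endpoint combining HbA1c change and
    medication change, OGTT-derived insulin-sensitivity indices (Matsuda,
    insulinogenic, disposition), stratified permuted-block randomisation,
    the trial statistical layer (chi-squared/Fisher contingency testing
    with expected-count-based test selection, Benjamini-Hochberg
    correction, linear mixed-model treatment effects, intention-to-treat
    and per-protocol analysis sets), and a synthetic longitudinal cohort
    generator with a caricature prescribing policy and missing-at-random
    dropout, so that every stage of the pipeline is testable without
    access to participant-level trial data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
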