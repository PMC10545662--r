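Package: exomereval
Title: Re-Evaluation and Re-Analysis Accounting for Exome Screening Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for systematic re-evaluation of published rare-disease exome
    cohorts. Implements ACMG/AMP evidence-criteria parsing with ACGS strength
    modifiers and two classification engines (the Tavtigian-style points system
    and the 2015 rule-combination system), a literature-evidence rule for
    gene-disease association validity, the 3-step re-analysis triage screen
    (rare loss-of-function variants, known pathogenic variants, rare missense
    variants at known pathogenic residues), cohort-level transition and
    diagnostic-yield accounting, and a synthetic cohort generator emulating a
    consanguineous neurodevelopmental-disorder screening study for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    utils
Suggests:
    dplyr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
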