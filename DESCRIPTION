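Package: vacoder
Title: Probabilistic Cause-of-Death Coding for Verbal Autopsy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A knowledge-base-driven probabilistic engine for interpreting
    verbal autopsy (VA) interview records. Each record of binary
    symptom/circumstance indicators is combined with a matrix of letter-graded
    conditional probabilities to assign a pregnancy status, up to three
    WHO-2016 causes of death with likelihoods, and a circumstance-of-mortality
    category. Input can follow the WHO-2016 indicator standard or its WHO-2012
    and Tariff-2 subsets; records are harmonised and consistency-checked
    before processing. Individual assignments aggregate into cause-specific
    mortality fractions (CSMFs) by age group, with proportional
    redistribution of indeterminate mass, cause amalgamation and broad-group
    rollups, and CSMF tables are compared with Lin's concordance correlation
    coefficient. A seeded simulator generates knowledge bases and cohorts
    with known cause composition so the whole pipeline can be validated
    against planted truth.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
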