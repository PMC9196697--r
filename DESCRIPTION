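Package: cohortcriteria
Title: Parse Clinical-Trial Eligibility Criteria into Executable Cohort Queries
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Parses free-text clinical-trial eligibility criteria into a
    structured JSON representation (entities, mapped vocabulary concepts,
    negation status, normalized temporal windows and value constraints),
    exposes a programmatic human-in-the-loop editing API with a replayable
    interaction log, and compiles the representation into cohort SQL over an
    OMOP-CDM-shaped relational store with demographic summarization.
    Includes deterministic generators for annotated criteria corpora and
    synthetic OMOP-lite databases with planted ground-truth cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    DBI,
    RSQLite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
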