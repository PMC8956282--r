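Package: pcattach
Title: Patient Attachment to Primary Care Providers from Health Administrative Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies every person in a population as attached or uncertainly
    attached to a primary care provider (PCP) using administrative data, via a
    hierarchical algorithm: formal enrollment (rostering), community health
    centre use, and plurality-of-visits virtual enrollment gated by a provider
    continuity-of-care (CoC) index. Includes a survey-based validation harness
    (confusion table, sensitivity/specificity/PPV/NPV, cohort splitting,
    CoC cut-point sensitivity analysis), a synthetic administrative-data
    generator that emulates claims, rosters, community health centre and
    hospital encounters and survey self-report, and a command-line front end
    for reproducible simulate/attach/validate runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1),
    tibble,
    rlang,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
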