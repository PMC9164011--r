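Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Maintainer", "pvsignal", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Case/non-case disproportionality analysis for spontaneous
    reporting (pharmacovigilance) databases. Provides a report-level data
    model for individual case safety reports, 2x2 contingency construction
    for drugs and drug groups, the Reporting Odds Ratio (ROR) with Woolf
    confidence intervals, the shrunken Information Component (IC) with the
    IC025 signal criterion (closed form cross-checked by a gamma-posterior
    Monte-Carlo oracle), eligibility filtering, subgroup and sensitivity
    strata, Table-1 style descriptive summaries, and a seeded synthetic
    database generator with signal injection for validation without access
    to restricted safety databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
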