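Package: msrelapse
Title: Claims-Based Relapse and Persistence Outcomes in Multiple
    Sclerosis Therapy-Switch Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for matched-cohort analyses of multiple
    sclerosis relapse outcomes in administrative claims data. Implements a
    claims-based relapse algorithm (inpatient primary ICD-9 340 rule,
    outpatient visit plus corticosteroid rule with exclusionary diagnoses,
    30-day event collapsing), medication persistence with a days-supply
    runout and 60-day gap rule, cohort selection with an auditable
    attrition table, stratified 1:1 nearest-neighbor propensity-score
    matching with a caliper, and outcome models fitted by generalized
    estimating equations (logistic and negative-binomial with a log
    exposure offset, pair-clustered robust variance), plus Kaplan-Meier
    time to first relapse with the log-rank test. A seeded synthetic
    claims generator with known ground truth makes every stage testable
    without access to licensed claims databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    MASS,
    survival,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
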