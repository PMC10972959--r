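Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    FAERS-style spontaneous adverse-event report databases. Reads the
    "$"-delimited quarterly ASCII tables (DEMO, DRUG, REAC, OUTC, INDI,
    THER), deduplicates case versions by the FDA-recommended most-recent
    FDA_DT rule, builds drug cohorts with primary-suspect and indication
    filters, and screens adverse events at the MedDRA preferred-term or
    system-organ-class level with four disproportionality algorithms
    (reporting odds ratio, proportional reporting ratio with Pearson
    chi-square, relative reporting ratio with a log-normal lower bound,
    and the information component) under a consensus signal-calling rule.
    Includes descriptive clinical profiling, time-to-onset analysis,
    indication-restricted re-screening with confounding checks, and a
    seeded synthetic-report generator with a ground-truth manifest so the
    whole pipeline is testable without downloading data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
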