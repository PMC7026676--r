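Package: prostcea
Title: Markov Microsimulation Cost-Effectiveness Model for Localized
    Prostate Cancer Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A six-state Markov model comparing active monitoring,
    radical prostatectomy, and external-beam radiotherapy with
    neoadjuvant hormone therapy for clinically localized prostate
    cancer over a 10-year horizon in 6-month cycles. Provides a
    deterministic cohort engine and a seeded patient-level
    microsimulation, discounted cost and QALY accounting,
    cost-effectiveness statistics (dominance frontier, ICER, net
    monetary benefit, acceptability curves), one-way and probabilistic
    sensitivity analysis, and calibration of unobserved inputs to
    published aggregate outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
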