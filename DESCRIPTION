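Package: psptree
Title: Decision-Tree Cost-Effectiveness Analysis of Spontaneous
    Pneumothorax Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A decision-analytic cost-effectiveness engine for emergency
    department management of moderate-to-large primary spontaneous
    pneumothorax (PSP). Four strategies (observation only, needle
    aspiration, small-bore chest tube with one-way valve, small-bore
    chest tube to suction) are compared by expected cost, lifetime
    discounted quality-adjusted life-years and net monetary benefit.
    Includes exact expected-value rollback of the decision tree, one-way
    (tornado) deterministic sensitivity analysis, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves,
    a patient-level microsimulation used as a validation oracle, and
    CSV report writers. Model inputs are supplied through a declarative
    YAML configuration; a base-case configuration (2022 USD costs,
    pooled trial success probabilities, published utility weights) is
    packaged.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
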