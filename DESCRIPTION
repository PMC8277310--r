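Package: metspace
Title: Personalized Nutrition Pipeline for Pre-Metabolic-Syndrome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening, scoring and evaluating personalized dietary
    interventions in adults at risk of metabolic syndrome (MetS). Implements
    MetS risk-factor flagging and at-risk/MetS classification with configurable
    thresholds, Dutch Healthy Diet Index (DHDI) category and total scoring,
    a "health space" personal health score (robust rank aggregation for
    healthy-reference selection plus a two-group multivariate mixed-model
    projection), a rule-based stage-1 dietary-advice engine with full reason
    provenance, longitudinal evaluation statistics (linear mixed models with
    a 3xRMSE outlier rule, Benjamini-Hochberg post hoc contrasts, ordinal
    mixed regression for Likert outcomes, delta correlations with influence
    screening), and a seeded synthetic-cohort generator that emulates the
    reference groups and week 0/8/16 intervention trajectories the analysis
    assumes, so the whole pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
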