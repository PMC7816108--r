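Package: ceahcc
Title: Cost-Effectiveness of Second-Line Pembrolizumab in Advanced
    Hepatocellular Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, config-driven re-implementation of a published
    cost-effectiveness analysis of pembrolizumab versus placebo as
    second-line therapy for advanced hepatocellular carcinoma. Provides
    Kaplan-Meier pseudo-individual-patient-data reconstruction from
    digitized survival curves and number-at-risk tables, parametric
    survival fitting with AIC selection and direct Weibull calibration
    from printed summary statistics, a 3-state (progression-free,
    postprogression, death) Markov cohort model with 3-week cycles,
    half-cycle correction and life-table background mortality, cost and
    quality-adjusted life-year accrual, and a full sensitivity-analysis
    suite: one-way and two-way deterministic analyses, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves,
    value-based price threshold search, and cure/dose-schedule/time-horizon
    scenario analyses. A synthetic-data module generates trial-like
    inputs (survival draws, digitized curves, risk tables, life tables)
    from known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    jsonlite,
    stats,
    tools,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
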