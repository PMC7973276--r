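Package: immunomark
Title: Predictive Immune Biomarker Modeling for Small Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for transcriptomic immune-profiling biomarker analysis in
    small clinical cohorts: single-analyte linear-threshold classifiers with
    leave-one-out evaluation, a multidimensional random-forest biomarker built
    by exhaustive feature-subset search and hyperparameter grid search,
    nonparametric trend and correlation statistics across ordered outcome
    groups, Kaplan-Meier and log-rank survival comparisons with hazard ratios,
    and a seeded synthetic cohort generator that emulates the statistical
    structure of tumor immune-profiling data (log-normal transcript
    abundances, compositional immune cell fractions, censored survival).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
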