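Package: dbEnsembles
Title: Ensembles of Single-Database Prognostic Models and Their Transportability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how binary prognostic models trained on
    separate observational healthcare databases can be combined and how well
    the combinations transport to databases they were not trained on.
    Provides a generator of heterogeneous synthetic claims-style databases
    (covariate shift, age truncation, outcome-rate shift), LASSO-penalized
    logistic Level-1 models with portable JSON model cards, seven Level-2
    ensemble schemes (mean, two AUROC-weighted fusions, case-mix similarity,
    age similarity, an age-gated mixture of experts, and stacking under
    label budgets), discrimination and calibration metrics, and a
    leave-one-database-out experiment runner that benchmarks every method
    against the internal validation of a model trained inside the held-out
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
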