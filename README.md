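# dbEnsembles

Prognostic models trained on a single observational healthcare database
often lose performance when transported to a different database or clinical
setting. Sharing patient-level data to train one pooled model is rarely
possible, but sharing *fitted models* is — a one-shot federated strategy in
which each site trains its own model and the models are combined afterwards.
`dbEnsembles` is an R package for studying, on fully synthetic data, how
well such combinations transport. It is aimed at methodologists working on
clinical risk prediction across database networks.

The package provides:

* a generator of heterogeneous claims-style databases — shifted age
  distributions (including one population capped at age 65 and one
  restricted to 65+), shifted feature prevalences, and outcome rates
  spanning rare to common — under one shared logistic outcome model;
* per-database **Level-1 models**: LASSO-penalized logistic regressions with
  the penalty selected by 3-fold stratified cross-validation maximizing
  AUROC, exported as portable JSON *model cards* (coefficients, internal
  AUROC, development feature means, development mean age);
* seven **Level-2 ensembles** over the cards for one outcome. With
  application feature means *d*, application mean age μ, and member
  development summaries (AUROC_i, d_i, age_i):

  | scheme | weight w_i |
  |---|---|
  | `mean`  | 1/N |
  | `auc1`  | \|AUROC_i − 0.5\| / Σ_k \|AUROC_k − 0.5\| |
  | `auc2`  | (AUROC_i − 0.5) / 0.5, unnormalized |
  | `sim`   | cos(d, d_i) / Σ_k cos(d, d_k) |
  | `age`   | s(μ, age_i) / Σ_k s(μ, age_k), s(a,b) = 1/(1+\|a−b\|) |
  | `ageME` | per-patient one-hot gate on argmin_i \|age_i − patient age\| |
  | stacking (`s|1000`, `s|10000`, `s|All`) | logistic regression on member risks, fitted on a label budget from the application database |

  The fused risk is Σ_i w_i f_ij(x) per patient;
* discrimination and calibration metrics (rank-based AUROC plus an
  exhaustive pairwise oracle, calibration-in-the-large, a quantile-binned
  calibration gradient);
* a **leave-one-database-out** runner: each database is held out in turn,
  models from the rest are evaluated on all of its patients, and every
  method is compared with the *internal benchmark* — the internal validation
  of a model trained inside the held-out database — via
  `AUROC_difference = externalAUROC − internalAUROC`.

## Worked example

Four synthetic databases, one 3% outcome; train cards on three of them and
transport to the fourth:

```r
library(dbEnsembles)

scen <- default_scenario(n_databases = 4, n_features = 30, seed = 7,
                         n_patients = 5000, outcome_rates = c(insomnia = 0.03))
dbs <- simulate_scenario(scen, seed = 7)

cards <- lapply(dbs[1:3], train_database_model, outcome_id = "insomnia", seed = 7)
cards[["db03"]]
#> <model_card> db 'db03', outcome 'insomnia': internal AUROC 0.600, 36 included features, dev mean age 78.8

ctx <- application_context(dbs[["db04"]])
w <- compute_fusion_weights("age", cards, ctx)
w
#> <fusion_weights> scheme 'age'
#>   db01   db02   db03
#> 0.4893 0.3460 0.1647
```

The age-similarity weights favour db01 and db02, whose development mean ages
sit closest to db04's mean age; the 65+ Medicare-like db03 (mean age 78.8)
gets the smallest weight. Applying the fused model to the unseen database:

```r
preds <- sapply(cards, predict_risk, features = dbs[["db04"]])
fused <- apply_fusion(w, preds)
auroc(fused, dbs[["db04"]]$labels$insomnia)
#> 0.595
calibration_in_the_large(fused, dbs[["db04"]]$labels$insomnia)
#> 0.0626
```

The transported ensemble discriminates (AUROC 0.595, close to db03's
internal 0.600) but under-predicts risk by 6.3 percentage points — the
typical pattern: discrimination transports, calibration does not. The full
leave-one-database-out experiment over all four databases:

```r
res <- run_lodo(dbs, lodo_config(seed = 7))
res
#> <lodo_result> 52 rows: 4 held-out databases x 1 outcomes x 14 methods (0 skipped)

s <- summary(res)
head(s[s$metric == "auroc_difference", ], 4)
#>  heldout_db method method_class           metric n   min    q1 median    q3   max
#>        db01   db02       single auroc_difference 1 0.106 0.106  0.106 0.106 0.106
#>        db01   db03       single auroc_difference 1 0.127 0.127  0.127 0.127 0.127
#>        db01   db04       single auroc_difference 1 0.086 0.086  0.086 0.086 0.086
#>        db01   mean       fusion auroc_difference 1 0.126 0.126  0.126 0.126 0.126
```

Each row is one (held-out database, method) cell: here every transported
method beats db01's internal benchmark (positive differences), because db01
has this scenario's lowest event rate and its internal model is trained on
few events. `headline_check(res)` reports the qualitative flags (fusion vs
single models, stacking under label budgets) with their supporting numbers,
and `plot(res)` draws the boxplot panel. At the package's default study
scale — five databases of 20,000 patients and rare/medium/common outcomes —
use `default_scenario()` with no size arguments, as in the vignette.

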