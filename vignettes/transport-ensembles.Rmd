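---
title: "Cross-database ensembles and model transportability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-database ensembles and model transportability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbEnsembles)
```

## The problem

A prognostic model trained on one observational healthcare database often
loses performance when applied to another database or clinical setting,
because populations differ in case mix, age structure and outcome rates.
Patient-level data usually cannot leave its home institution, but fitted
models can. A practical one-shot federated strategy is therefore: train one
model per database, share only the models, and combine them. `dbEnsembles`
implements this strategy end to end on synthetic data so the behaviour of
each combination rule can be studied quantitatively.

Throughout, a *Level-1 model* $f_{ij}$ is a LASSO-penalized logistic
regression trained on database $i$ for binary outcome $j$, mapping a sparse
binary feature vector (condition/drug indicators, 5-year age-bin indicators,
a male indicator) to a risk in $[0,1]$. A *Level-2 ensemble* combines the
$N$ Level-1 models for the same outcome.

## Data-generating model

The generator draws $K$ databases from one shared logistic outcome model,

$$\Pr(y = 1 \mid x) = \mathrm{expit}\big(\beta_{0j} + s_k + x^\top \beta\big),$$

where $\beta$ is shared across databases and outcomes, $\beta_{0j}$ sets
each outcome's baseline rate and $s_k$ is a database-specific intercept
shift. Databases differ in:

* **age structure** — truncated-normal ages with means spanning 35–75 years;
  one population is capped at age 65 (commercially insured) and the
  oldest-mean population is restricted to 65 and over (Medicare-like), so
  some age strata are simply unobservable in some databases;
* **case mix** — per-database log-odds shifts of the indicator-feature
  prevalences, applied on the logit scale so probabilities stay in $(0,1)$;
* **outcome rates** — the intercept shifts $s_k$, evenly spaced on
  $[-1, 1]$, which at the default baseline rates (0.15%, 1%, 5%) spread the
  realized database–outcome rates over roughly 0.05%–14%.

Keeping $\beta$ shared is deliberate: every Level-1 model then estimates the
*same* conditional risk surface, heterogeneity enters only through covariate
shift and the outcome rate, and the internal benchmark (below) is a
meaningful upper bound. This isolates the mechanism by which differing
outcome rates and unobserved strata degrade transported models, at the price
of removing real-world model misspecification (see Limitations).

The default study scenario uses 5 databases of 20,000 patients, 50
indicator features and three outcomes (rare / medium / common). These sizes
are the package's desk-scale stand-in for a full multi-database study with
dozens of outcomes; they keep a complete leave-one-database-out experiment
in the low minutes on a single core while leaving enough events to train
rare-outcome models. Independence across indicator features is assumed — the
joint dependence structure of real claims features is not modelled.

## Level-1 training

Each (database, outcome) model is trained on a stratified 80/20 split.
The LASSO penalty is selected by 3-fold stratified cross-validation over a
fixed log-spaced grid of 25 strengths spanning $10^{-4}$–$10^{2}$,
maximizing the mean out-of-fold AUROC (discrimination, not likelihood); ties
go to the strongest penalty, i.e. the most parsimonious model. The final
model is refit on the full 80% at the selected penalty. Stratification of
both the split and the folds is an implementation choice that guarantees
events in every fold for rare outcomes. Because all predictors are 0/1
indicators, no standardization is applied and the penalty acts on the raw
log-odds scale; the intercept is never penalized. At the top of the default
grid the model is provably intercept-only, which gives the search a
well-defined "no signal" end point.

What travels between databases is a **model card**: coefficients, intercept,
selected penalty, internal validation on the 20% split (AUROC,
calibration-in-the-large, calibration gradient), the development means of
the model's included (nonzero-coefficient) features, the development mean
age in years, the training outcome rate, and the split sizes. Every ensemble
below is computable from cards plus application-side summaries — no
patient-level development data crosses database boundaries.

When a model is applied to a database whose columns do not fully match,
alignment is by column name and absent columns contribute zero: an
unobserved stratum carries no signal, which is exactly the failure mode the
age-truncated databases create.

## The seven ensembles

With member cards $i = 1, \dots, N$ (the same outcome, distinct databases)
and application context $d$ (feature means), $\mu_{\text{age}}$ (mean age):

| scheme | weight $w_i$ | needs labels? |
|---|---|---|
| mean | $1/N$ | no |
| auc1 | $\lvert \mathrm{AUROC}_i - 0.5\rvert \big/ \sum_k \lvert \mathrm{AUROC}_k - 0.5\rvert$ | no |
| auc2 | $(\mathrm{AUROC}_i - 0.5)/0.5$, **not** normalized | no |
| sim | $\cos(d, d_i) \big/ \sum_k \cos(d, d_k)$ | no |
| age | $s(\mu_{\text{age}}, \text{age}_i) \big/ \sum_k s(\mu_{\text{age}}, \text{age}_k)$, $s(a,b) = 1/(1+\lvert a-b\rvert)$ | no |
| ageME | per-patient one-hot gate on $\arg\min_i \lvert \text{age}_i - \text{age}\rvert$ | no |
| stacking | logistic regression on the member risks | yes |

The fused prediction is $\sum_i w_i f_{ij}(x)$ per patient. Design points
that were genuinely open and how they were resolved:

* **sim feature sets.** "The features included in model $i$" is read as that
  model's nonzero-coefficient features: each member's cosine compares the
  application means with its development means *over its own subset*, and
  the cosines are then normalized jointly. A card with no included features
  has an undefined cosine and is excluded (cosine 0) with a warning. The
  alternative reading — one shared feature vector for all members — is not
  what the per-model development means support, so it was not implemented.
* **auc2 is unclamped.** Its weights do not sum to 1, so fused values can
  leave $[0,1]$. They are evaluated as-is by all metrics; the point of
  carrying this scheme is precisely to expose the calibration damage
  unnormalized weights cause.
* **ageME gating** uses the absolute age difference. A signed minimum would
  always select the youngest development population regardless of the
  patient, which contradicts the scheme's stated intent ("most closely
  matches"); ties break to the lexicographically smallest database id so
  runs are deterministic.
* **Stacking inputs are raw risks**, not logits (a logit-input variant is
  available behind `use_logit = TRUE`, off by default). The label subsample
  is simple random, *unstratified*, and seeded: with a 1,000-label budget
  and a 0.1% outcome the subsample frequently contains no events, and that
  failure is the scheme's documented behaviour — it surfaces as an explicit
  skip record, never a silent drop. The logistic MLE is fitted with a tight
  convergence tolerance (`epsilon = 1e-12`, up to 100 IRLS iterations) so
  the score equation — mean fitted risk equals the subsample event rate —
  holds to at least `1e-8`; quasi-separation is flagged on the returned
  object rather than raised.
* **No member rescaling and no pruning.** Both would change what is being
  measured (they are follow-on methods, not part of the seven schemes).

Degenerate weight inputs fall back predictably: if every auc1 numerator is
zero (all member AUROCs exactly 0.5) or every cosine is zero, the scheme
falls back to uniform weights with a warning rather than dividing by zero.

## Metrics

* **AUROC** is the rank-based (Mann–Whitney) estimate; tied predictions
  count 0.5 per pair. The package also ships the literal all-pairs
  implementation (`auroc_pairwise_oracle`) — quadratic, capped at
  n = 10,000 — kept deliberately independent so each can check the other.
* **Calibration-in-the-large** is observed event rate minus mean predicted
  risk (positive = under-prediction).
* **Calibration gradient** has no single canonical estimator; here patients
  are sorted into equal-count quantile bins (default 100; reduced to
  $\lfloor n/2 \rfloor$ when n is small so every bin holds at least two
  patients) and the gradient is the OLS slope of per-bin observed event
  fraction on per-bin mean prediction. The sign convention makes a gradient
  far above 1 mean "predicted risks are systematically too small": scaling
  correct predictions by $c = 0.1$ produces a slope near 10. A constant
  prediction vector has no defined slope and errors.

## The leave-one-database-out experiment

Each database $k$ is held out in turn. Level-1 models from the other
databases — each trained once per outcome and reused across folds — are
applied to *every* patient of database $k$, singly and through each
ensemble. The **internal benchmark** is the internal validation (20% test
split) of a model trained inside database $k$ itself; the headline quantity
is

$$\mathrm{AUROC\_difference} = \mathrm{externalAUROC} - \mathrm{internalAUROC},$$

near-zero values meaning the transported model matches what a locally
trained model achieves. The asymmetry — external evaluation on the full
database, benchmark on its 20% split — is part of the design definition and
is kept. Stacking fits its Level-2 weights on a labelled subsample *of the
held-out database* and is then evaluated on the full database including that
subsample; a leakage-aware variant (`stacking_eval = "complement"`)
evaluates on the complement only and is off by default.

Every (held-out database, outcome, method) cell yields one tidy result row;
cells that cannot be computed (an outcome too rare to stratify, an
event-free stacking subsample, a single-class evaluation) become explicit
skip rows carrying the reason. `summarize_distributions()` produces the
five-number summaries behind the usual boxplot panels, and
`headline_check()` reports four qualitative flags — mean fusion's median
transport gap at least matching every single-database model, its IQR no
wider than the pooled single-model IQR, small-budget stacking degrading on
the rare outcome, and full-label stacking achieving the smallest median
|calibration-in-the-large|. The flags are *reported* at run time; the test
suite asserts them under the pinned default seed.

## Determinism

Every stochastic step (scenario construction, simulation, splits, CV folds,
stacking subsamples) takes an explicit seed, derives stage seeds from it
arithmetically, and restores the caller's RNG state afterwards. Two runs of
the full pipeline with the same configuration produce byte-identical result
tables; this is tested.

## Limitations

* The shared-coefficient world means a single-database model is correctly
  specified for every other database; transported models lose discrimination
  only through unobserved age strata and estimation noise, not through the
  model-level misspecification real cross-database transport also suffers.
  Fusion's advantage over the *best-placed* single database is therefore
  thinner here than a practitioner should expect on real data, and at desk
  scale the pooled medians of the two can sit within sampling noise of each
  other (the rare outcome's internal benchmark rests on a handful of test
  events, making the reference itself volatile).
* Feature independence, Bernoulli indicators and normal ages are stylized;
  real claims features are strongly dependent and age distributions are not
  normal. Passing tests demonstrate the machinery and the mechanisms the
  generator encodes — not performance claims about any real database.
* Calibration conclusions depend on the binned-OLS gradient stand-in; other
  slope estimators (e.g. logistic recalibration slope on the logit scale)
  would give numerically different values.
* No confidence intervals, no recalibration procedures, no model pruning,
  and no alternative learners are provided.
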