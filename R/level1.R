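# Level-1 models: one LASSO-penalized logistic regression per
# (database, outcome), trained on an 80/20 stratified split with 3-fold
# cross-validation over a fixed penalty grid, selecting the penalty that
# maximizes mean CV AUROC.  The shareable artifact is a "model card": the
# coefficients plus the development-population summaries every ensemble
# scheme needs (internal AUROC, included-feature means, mean age), so
# ensembles never touch patient-level development data.

#' Default penalty grid
#'
#' 25 log-spaced penalty strengths spanning 1e-4 to 1e2. At the strongest
#' grid value all feature coefficients are shrunk to zero (intercept-only
#' model).
#'
#' @param n Number of grid points.
#' @param lo,hi Grid endpoints (penalty strength).
#' @return Numeric vector, increasing.
#' @export
default_penalty_grid <- function(n = 25, lo = 1e-4, hi = 1e2) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

outcome_labels <- function(ds, outcome_id) {
  y <- ds$labels[[outcome_id]]
  if (is.null(y)) stop("unknown outcome: ", outcome_id)
  y
}

#' Stratified train/test split
#'
#' Partitions a dataset into a development and a held-out split, stratified
#' by the outcome label so both splits contain events even when the outcome
#' is rare.
#'
#' @param ds A `labelled_dataset`.
#' @param outcome_id Outcome to stratify on.
#' @param test_fraction Fraction held out, strictly in (0,1); default 0.2.
#' @param seed Integer seed; the index partition is reproducible.
#' @return List with `train` and `test` (both `labelled_dataset`) and the
#'   held-out row indices `test_idx`.
#' @export
split_train_test <- function(ds, outcome_id, test_fraction = 0.2, seed = 1) {
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("'test_fraction' must lie strictly in (0,1)")
  y <- outcome_labels(ds, outcome_id)
  if (sum(y == 1) < 2)
    stop("cannot stratify: fewer than 2 events for outcome '", outcome_id, "'")
  if (sum(y == 0) < 2)
    stop("cannot stratify: fewer than 2 non-events for outcome '", outcome_id, "'")
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  n1_test <- round(length(idx1) * test_fraction)
  n0_test <- round(length(idx0) * test_fraction)
  if (n1_test == 0 || n0_test == 0 ||
      n1_test >= length(idx1) || n0_test >= length(idx0))
    stop("degenerate split: a class would be empty in train or test")
  test_idx <- local_seed(seed, {
    sort(c(sample(idx1, n1_test), sample(idx0, n0_test)))
  })
  list(train = subset_dataset(ds, -test_idx),
       test = subset_dataset(ds, test_idx),
       test_idx = test_idx)
}

# stratified fold assignment: within each class, cycle fold ids over a
# random permutation
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  local_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Fit a LASSO logistic regression with CV penalty selection
#'
#' Fits the L1-penalized logistic path over `penalty_grid` with glmnet,
#' selects the penalty maximizing the mean AUROC across `cv_folds` stratified
#' cross-validation folds (ties broken toward the strongest penalty, i.e. the
#' most parsimonious model), and refits on the full training data at the
#' selected penalty. Features are 0/1 indicators, so no standardization is
#' applied and the penalty acts on the raw log-odds scale; the intercept is
#' never penalized.
#'
#' @param train A `labelled_dataset` (the development split).
#' @param outcome_id Outcome to model.
#' @param penalty_grid Positive penalty strengths to search.
#' @param cv_folds Number of CV folds (default 3).
#' @param seed Integer seed for fold assignment.
#' @return An object of class `level1_model` with elements `db_id`,
#'   `outcome_id`, `coefficients` (named, zeros retained), `intercept`,
#'   `penalty`, `feature_names`, `cv_auroc` (per-grid-point mean CV AUROC).
#' @export
fit_lasso_logistic <- function(train, outcome_id,
                               penalty_grid = default_penalty_grid(),
                               cv_folds = 3, seed = 1) {
  if (length(penalty_grid) == 0 || any(penalty_grid <= 0))
    stop("'penalty_grid' must be non-empty with all strengths positive")
  y <- outcome_labels(train, outcome_id)
  if (length(unique(y)) < 2)
    stop("cannot fit: all labels identical for outcome '", outcome_id, "'")
  if (sum(y == 1) < cv_folds || sum(y == 0) < cv_folds)
    stop("cannot cross-validate: fewer events (or non-events) than folds")
  x <- train$features
  lambda <- sort(unique(penalty_grid), decreasing = TRUE)

  fold <- stratified_folds(y, cv_folds, seed)
  cv_auc <- matrix(NA_real_, nrow = cv_folds, ncol = length(lambda))
  for (f in seq_len(cv_folds)) {
    hold <- fold == f
    fit_f <- glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold],
                            family = "binomial", lambda = lambda,
                            standardize = FALSE)
    pred <- stats::predict(fit_f, newx = x[hold, , drop = FALSE],
                           s = lambda, type = "response", exact = FALSE)
    cv_auc[f, ] <- apply(pred, 2, function(p) auroc(p, y[hold]))
  }
  mean_auc <- colMeans(cv_auc)
  best <- max(mean_auc)
  # ties (within numerical noise) go to the strongest penalty = first index
  sel <- which(mean_auc >= best - 1e-12)[1]

  fit <- glmnet::glmnet(x, y, family = "binomial", lambda = lambda,
                        standardize = FALSE)
  cf <- stats::coef(fit, s = lambda[sel], exact = FALSE)
  coefs <- stats::setNames(as.numeric(cf[-1, 1]), rownames(cf)[-1])

  structure(
    list(db_id = train$db_id, outcome_id = outcome_id,
         coefficients = coefs, intercept = as.numeric(cf[1, 1]),
         penalty = lambda[sel], feature_names = colnames(x),
         cv_auroc = stats::setNames(mean_auc, signif(lambda, 6))),
    class = "level1_model")
}

#' @export
print.level1_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(
    "<level1_model> db '%s', outcome '%s': %d/%d nonzero coefficients, penalty %.4g\n",
    x$db_id, x$outcome_id, nz, length(x$coefficients), x$penalty))
  invisible(x)
}

#' @export
coef.level1_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

included_features <- function(object) {
  names(object$coefficients)[object$coefficients != 0]
}

# align a feature matrix to a model's feature names: match by column name,
# absent columns contribute zero (an unobserved stratum carries no signal)
align_features <- function(feature_names, features) {
  if (inherits(features, "labelled_dataset")) features <- features$features
  features <- as.matrix(features)
  present <- intersect(feature_names, colnames(features))
  if (length(present) == 0)
    stop("cannot align features: no overlap with the model's feature names")
  out <- matrix(0, nrow = nrow(features), ncol = length(feature_names),
                dimnames = list(NULL, feature_names))
  out[, present] <- features[, present, drop = FALSE]
  out
}

#' Predicted outcome risk from a Level-1 model (or model card)
#'
#' `plogis(intercept + x . coefficients)` per patient. Columns are aligned by
#' name; columns the model knows but the data lacks are treated as all-zero.
#'
#' @param model A `level1_model` or `model_card`.
#' @param features A feature matrix (or `labelled_dataset`).
#' @return Risk vector, strictly inside (0,1).
#' @export
predict_risk <- function(model, features) {
  x <- align_features(model$feature_names, features)
  stats::plogis(model$intercept + drop(x %*% model$coefficients))
}

#' @export
predict.level1_model <- function(object, newdata, ...) {
  predict_risk(object, newdata)
}

#' Assemble a portable model card
#'
#' Packages everything the ensemble schemes need without patient-level data:
#' the model itself, its internal validation on the 20% held-out split
#' (AUROC, calibration-in-the-large, calibration gradient), the development
#' means of the model's included (nonzero-coefficient) features, the
#' development mean age in years, and the training outcome rate. A model with
#' no included features is flagged `degenerate`.
#'
#' @param model A `level1_model`.
#' @param train,test The development and held-out `labelled_dataset` splits.
#' @return An object of class `model_card`.
#' @export
make_model_card <- function(model, train, test) {
  y_test <- outcome_labels(test, model$outcome_id)
  p_test <- predict_risk(model, test)
  grad <- tryCatch(calibration_gradient(p_test, y_test),
                   error = function(e) NA_real_)
  inc <- included_features(model)
  degenerate <- length(inc) == 0
  dev_means <- if (degenerate) stats::setNames(numeric(0), character(0))
               else population_feature_means(train, inc)
  structure(
    list(db_id = model$db_id, outcome_id = model$outcome_id,
         coefficients = model$coefficients, intercept = model$intercept,
         penalty = model$penalty, feature_names = model$feature_names,
         internal_auroc = auroc(p_test, y_test),
         internal_citl = calibration_in_the_large(p_test, y_test),
         internal_gradient = grad,
         dev_feature_means = dev_means,
         dev_mean_age = mean(train$age_years),
         dev_outcome_rate = mean(outcome_labels(train, model$outcome_id)),
         train_n = n_patients(train), test_n = n_patients(test),
         degenerate = degenerate),
    class = "model_card")
}

#' @export
print.model_card <- function(x, ...) {
  cat(sprintf(
    "<model_card> db '%s', outcome '%s': internal AUROC %.3f, %d included features, dev mean age %.1f%s\n",
    x$db_id, x$outcome_id, x$internal_auroc,
    length(x$dev_feature_means), x$dev_mean_age,
    if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' @export
predict.model_card <- function(object, newdata, ...) {
  predict_risk(object, newdata)
}

#' Train, validate and package one database model
#'
#' Convenience wrapper: stratified 80/20 split, CV-selected LASSO fit on the
#' development split, internal validation on the held-out split, model card
#' assembly.
#'
#' @inheritParams fit_lasso_logistic
#' @param ds A `labelled_dataset`.
#' @param test_fraction Held-out fraction (default 0.2).
#' @return A `model_card`.
#' @export
train_database_model <- function(ds, outcome_id, test_fraction = 0.2,
                                 penalty_grid = default_penalty_grid(),
                                 cv_folds = 3, seed = 1) {
  sp <- split_train_test(ds, outcome_id, test_fraction, seed = seed)
  model <- fit_lasso_logistic(sp$train, outcome_id, penalty_grid,
                              cv_folds = cv_folds, seed = seed + 1L)
  make_model_card(model, sp$train, sp$test)
}

#' Serialize / deserialize a model card as JSON
#'
#' Coefficients are stored sparsely (name -> value for nonzero entries only);
#' the full feature-name list is kept so alignment survives the round trip.
#'
#' @param card A `model_card`.
#' @param path JSON file path.
#' @return `write_model_card` returns `path` invisibly; `read_model_card`
#'   returns a `model_card` identical to the one written.
#' @export
write_model_card <- function(card, path) {
  nz <- card$coefficients[card$coefficients != 0]
  obj <- list(
    schema_version = 1L,
    db_id = card$db_id, outcome_id = card$outcome_id,
    feature_names = card$feature_names,
    coefficients = as.list(nz),
    intercept = card$intercept, penalty = card$penalty,
    internal_auroc = card$internal_auroc,
    internal_citl = card$internal_citl,
    internal_gradient = card$internal_gradient,
    dev_feature_means = as.list(card$dev_feature_means),
    dev_mean_age = card$dev_mean_age,
    dev_outcome_rate = card$dev_outcome_rate,
    train_n = card$train_n, test_n = card$test_n,
    degenerate = card$degenerate)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_card
#' @export
read_model_card <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- stats::setNames(rep(0, length(obj$feature_names)), obj$feature_names)
  if (length(obj$coefficients))
    coefs[names(obj$coefficients)] <- unlist(obj$coefficients)
  dev_means <- if (length(obj$dev_feature_means))
    unlist(obj$dev_feature_means) else stats::setNames(numeric(0), character(0))
  structure(
    list(db_id = obj$db_id, outcome_id = obj$outcome_id,
         coefficients = coefs, intercept = obj$intercept,
         penalty = obj$penalty, feature_names = obj$feature_names,
         internal_auroc = obj$internal_auroc,
         internal_citl = obj$internal_citl,
         internal_gradient = if (is.null(obj$internal_gradient)) NA_real_
                             else obj$internal_gradient,
         dev_feature_means = dev_means,
         dev_mean_age = obj$dev_mean_age,
         dev_outcome_rate = obj$dev_outcome_rate,
         train_n = obj$train_n, test_n = obj$test_n,
         degenerate = obj$degenerate),
    class = "model_card")
}
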