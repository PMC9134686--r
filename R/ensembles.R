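# Level-2 ensembles: combine N Level-1 model cards that predict the same
# outcome.  Five fixed-weight fusions (mean, two AUROC weightings, case-mix
# cosine similarity, age similarity), one per-patient mixture of experts
# gated on age, and a stacking logistic regression fitted on labelled data
# from the application database under a label budget.

check_cards <- function(cards, min_cards = 2) {
  if (length(cards) < min_cards)
    stop("need at least ", min_cards, " model cards")
  if (!all(vapply(cards, inherits, logical(1), "model_card")))
    stop("all members must be model_card objects")
  ids <- vapply(cards, `[[`, character(1), "db_id")
  if (anyDuplicated(ids)) stop("member db_ids must be distinct")
  outs <- unique(vapply(cards, `[[`, character(1), "outcome_id"))
  if (length(outs) != 1)
    stop("all member cards must predict the same outcome")
  ids
}

#' Application-side context for data-dependent weighting
#'
#' Summaries of the dataset an ensemble is being applied to: the per-feature
#' means (for case-mix similarity weighting), the mean age in years (for age
#' similarity weighting) and the per-patient ages (for the age-gated mixture
#' of experts).
#'
#' @param ds A `labelled_dataset`.
#' @return An object of class `application_context`.
#' @export
application_context <- function(ds) {
  structure(
    list(feature_means = colMeans(ds$features),
         mean_age = mean(ds$age_years),
         ages = ds$age_years),
    class = "application_context")
}

cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Fusion weights for a set of model cards
#'
#' Computes one weight per member model under the requested scheme:
#' \describe{
#'   \item{mean}{`w_i = 1/N` (uniform).}
#'   \item{auc1}{`w_i = |AUROC_i - 0.5| / sum_k |AUROC_k - 0.5|` — internal
#'     discrimination scaled relative to chance and normalized.}
#'   \item{auc2}{`w_i = (AUROC_i - 0.5) / 0.5` — scaled between 1 (perfect)
#'     and -1 (perfectly anti-ranking), NOT normalized; the weighted sum can
#'     leave \[0,1\] and is returned unclamped downstream.}
#'   \item{sim}{`w_i = cosine(d, d_i) / sum_k cosine(d, d_k)` where `d_i` is
#'     the development means of model i's included features and `d` is the
#'     application-population means of those same features (each model uses
#'     its own included-feature subset).}
#'   \item{age}{`w_i = s(mu, age_i) / sum_k s(mu, age_k)` with
#'     `s(a, b) = 1 / (1 + |a - b|)`, `mu` the application mean age and
#'     `age_i` the development mean age, both in years.}
#' }
#' Degenerate cases: if every numerator is zero (all AUROCs exactly 0.5, or
#' all cosines 0) the scheme falls back to uniform weights with a warning.
#' A degenerate card (no included features) gets cosine 0 under `sim`, i.e.
#' is excluded, with a warning.
#'
#' @param scheme One of `"mean"`, `"auc1"`, `"auc2"`, `"sim"`, `"age"`.
#' @param cards List of `model_card`s for the same outcome, distinct db_ids.
#' @param context An [application_context()]; required for `sim` and `age`.
#' @return An object of class `fusion_weights`: list with `weights` (named by
#'   db_id), `scheme`, `fallback` (logical).
#' @export
compute_fusion_weights <- function(scheme = c("mean", "auc1", "auc2", "sim", "age"),
                                   cards, context = NULL) {
  scheme <- match.arg(scheme)
  ids <- check_cards(cards)
  n <- length(cards)
  fallback <- FALSE

  if (scheme %in% c("sim", "age") && is.null(context))
    stop("scheme '", scheme, "' requires an application_context")

  w <- switch(scheme,
    mean = rep(1 / n, n),
    auc1 = {
      a <- vapply(cards, `[[`, numeric(1), "internal_auroc")
      num <- abs(a - 0.5)
      if (sum(num) == 0) {
        warning("all internal AUROCs are exactly 0.5; falling back to uniform weights")
        fallback <- TRUE
        rep(1 / n, n)
      } else num / sum(num)
    },
    auc2 = {
      a <- vapply(cards, `[[`, numeric(1), "internal_auroc")
      (a - 0.5) / 0.5
    },
    sim = {
      cs <- vapply(cards, function(card) {
        if (isTRUE(card$degenerate) || length(card$dev_feature_means) == 0) {
          warning("degenerate card '", card$db_id,
                  "' has no included features; cosine set to 0 (excluded)")
          return(0)
        }
        feats <- names(card$dev_feature_means)
        missing <- setdiff(feats, names(context$feature_means))
        if (length(missing))
          stop("application context lacks features: ",
               paste(missing, collapse = ", "))
        cosine(context$feature_means[feats], card$dev_feature_means)
      }, numeric(1))
      if (sum(cs) == 0) {
        warning("all case-mix cosines are 0; falling back to uniform weights")
        fallback <- TRUE
        rep(1 / n, n)
      } else cs / sum(cs)
    },
    age = {
      ages <- vapply(cards, `[[`, numeric(1), "dev_mean_age")
      s <- 1 / (1 + abs(context$mean_age - ages))
      s / sum(s)
    })

  structure(list(weights = stats::setNames(w, ids), scheme = scheme,
                 fallback = fallback),
            class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat(sprintf("<fusion_weights> scheme '%s'%s\n", x$scheme,
              if (x$fallback) " (uniform fallback)" else ""))
  print(round(x$weights, 4))
  invisible(x)
}

# coerce member predictions (named list of vectors or matrix with db_id
# columns) into an n x N matrix
member_matrix <- function(member_predictions, ids) {
  m <- if (is.list(member_predictions)) {
    lens <- lengths(member_predictions)
    if (length(unique(lens)) != 1)
      stop("member predictions must cover the same patients")
    do.call(cbind, member_predictions)
  } else as.matrix(member_predictions)
  if (is.null(colnames(m))) stop("member predictions must be named by db_id")
  missing <- setdiff(ids, colnames(m))
  if (length(missing))
    stop("member predictions missing for: ", paste(missing, collapse = ", "))
  m[, ids, drop = FALSE]
}

#' Apply fixed fusion weights to member predictions
#'
#' Per-patient weighted sum `sum_i w_i f_i(x)`. For the normalized schemes
#' the output stays in \[0,1\] whenever the member predictions do; for the
#' unnormalized `auc2` scheme the output may leave \[0,1\] and is returned
#' unclamped.
#'
#' @param w A [compute_fusion_weights()] result.
#' @param member_predictions Named list of per-model risk vectors (or a
#'   matrix with db_id column names), aligned on the same patients.
#' @return Numeric vector of fused predictions.
#' @export
apply_fusion <- function(w, member_predictions) {
  stopifnot(inherits(w, "fusion_weights"))
  m <- member_matrix(member_predictions, names(w$weights))
  drop(m %*% w$weights)
}

#' Age-gated mixture-of-experts weights
#'
#' For each patient, weight 1 on the member whose development-population mean
#' age most closely matches the patient's age (argmin of the absolute
#' difference), 0 on all others. Ties are broken toward the lexicographically
#' smallest db_id, deterministically.
#'
#' @param cards List of `model_card`s (>= 2) with `dev_mean_age` present.
#' @param patient_ages Ages in years of the patients being predicted.
#' @return An `n x N` one-hot matrix with db_id column names.
#' @export
age_mixture_gate <- function(cards, patient_ages) {
  ids <- check_cards(cards)
  if (length(patient_ages) == 0 || anyNA(patient_ages))
    stop("patient ages are missing")
  ages <- vapply(cards, `[[`, numeric(1), "dev_mean_age")
  if (anyNA(ages)) stop("a member card lacks dev_mean_age")
  ord <- order(ids)  # lexicographic tie-break
  d <- abs(outer(patient_ages, ages[ord], "-"))
  pick <- ord[max.col(-d, ties.method = "first")]
  g <- matrix(0, nrow = length(patient_ages), ncol = length(cards),
              dimnames = list(NULL, ids))
  g[cbind(seq_along(patient_ages), pick)] <- 1
  g
}

#' Predict with the age-gated mixture of experts
#'
#' Each patient's risk is exactly the prediction of the single member model
#' selected by [age_mixture_gate()].
#'
#' @inheritParams age_mixture_gate
#' @inheritParams apply_fusion
#' @return Numeric risk vector.
#' @export
predict_age_mixture <- function(cards, member_predictions, patient_ages) {
  ids <- check_cards(cards)
  g <- age_mixture_gate(cards, patient_ages)
  m <- member_matrix(member_predictions, ids)
  if (nrow(m) != nrow(g))
    stop("member predictions and patient ages must cover the same patients")
  rowSums(g * m)
}

#' Fit a stacking (Level-2) logistic regression
#'
#' Draws a simple random subsample of `n_labels` patients from the
#' application dataset (unstratified — rare outcomes can and do yield
#' event-free subsamples, which is the scheme's known failure mode), computes
#' each member's predicted risk on the subsample, and fits an unpenalized
#' logistic regression of the outcome on the member risk columns plus an
#' intercept. Effectively this learns the member weightings, and because it
#' is a logistic MLE its mean fitted risk equals the subsample event rate
#' (calibration-in-the-large 0 on the fitting sample).
#'
#' @param cards List of `model_card`s for the same outcome.
#' @param application_sample A `labelled_dataset` from the application
#'   database, with labels for the cards' outcome.
#' @param n_labels Label budget: positive integer or `"all"`.
#' @param seed Integer seed for the subsample.
#' @param use_logit If `TRUE`, member risks enter on the logit scale instead
#'   of the risk scale (off by default; the risk scale is the primary
#'   definition).
#' @return An object of class `stacking_model`: member coefficients keyed by
#'   db_id, `intercept`, `n_labels_used`, `n_events`, `separation` flag,
#'   `use_logit`, `outcome_id`.
#' @export
fit_stacking <- function(cards, application_sample, n_labels = "all",
                         seed = 1, use_logit = FALSE) {
  ids <- check_cards(cards)
  outcome_id <- cards[[1]]$outcome_id
  n <- n_patients(application_sample)
  if (identical(n_labels, "all")) n_labels <- n
  if (!(is.numeric(n_labels) && length(n_labels) == 1 && n_labels >= 1))
    stop("'n_labels' must be a positive integer or \"all\"")
  if (n_labels > n)
    stop("'n_labels' exceeds the application sample size")
  idx <- local_seed(seed, sample.int(n, n_labels))
  sub <- subset_dataset(application_sample, idx)
  y <- outcome_labels(sub, outcome_id)
  if (sum(y == 1) == 0)
    stop("no events in the stacking subsample (label budget too small for this outcome)")
  if (sum(y == 0) == 0)
    stop("no non-events in the stacking subsample")

  risk <- vapply(cards, function(card) predict_risk(card, sub), numeric(n_labels))
  colnames(risk) <- ids
  xin <- if (use_logit) stats::qlogis(pmin(pmax(risk, 1e-12), 1 - 1e-12)) else risk
  df <- data.frame(y = y, xin, check.names = FALSE)

  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation)
    warning("quasi-separation in stacking fit; coefficients capped by optimizer tolerance")

  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0  # collinear member dropped by glm contributes nothing
  structure(
    list(coefficients = stats::setNames(cf[-1], ids),
         intercept = unname(cf[1]),
         n_labels_used = as.integer(n_labels),
         n_events = sum(y == 1),
         separation = separation,
         use_logit = use_logit,
         outcome_id = outcome_id,
         member_ids = ids),
    class = "stacking_model")
}

#' @export
print.stacking_model <- function(x, ...) {
  cat(sprintf(
    "<stacking_model> outcome '%s': %d members, %d labels (%d events)%s\n",
    x$outcome_id, length(x$coefficients), x$n_labels_used, x$n_events,
    if (x$separation) " [separation flagged]" else ""))
  print(round(c("(Intercept)" = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' @export
coef.stacking_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict from a fitted stacking model
#'
#' `plogis(intercept + sum_i coef_i * risk_i)`; outputs lie strictly in
#' (0,1).
#'
#' @param stack A `stacking_model`.
#' @param member_predictions As in [apply_fusion()], keyed by db_id.
#' @return Numeric risk vector.
#' @export
predict_stacking <- function(stack, member_predictions) {
  stopifnot(inherits(stack, "stacking_model"))
  m <- member_matrix(member_predictions, stack$member_ids)
  if (stack$use_logit) m <- stats::qlogis(pmin(pmax(m, 1e-12), 1 - 1e-12))
  stats::plogis(stack$intercept + drop(m %*% stack$coefficients))
}

#' @export
predict.stacking_model <- function(object, newdata, ...) {
  predict_stacking(object, newdata)
}
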