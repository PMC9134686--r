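# Synthetic heterogeneous claims-style databases.
#
# A scenario is a shared outcome-generating logistic model (GroundTruth)
# plus K database profiles that shift the covariate distribution (feature
# prevalences, age distribution, age truncation) and the outcome rate
# (per-database intercept shift).  All heterogeneity in outcome rates enters
# through the intercept; the coefficient vector is shared, so a model trained
# in any database estimates the same conditional log-odds surface and the
# internal benchmark is a meaningful upper bound.

AGE_BIN_WIDTH <- 5
AGE_BIN_MAX <- 95  # last bin is [95, Inf)

#' Age-bin column names used throughout the package
#'
#' Half-open 5-year bins `[0,5), [5,10), ...` with a final open-ended
#' `[95, Inf)` bin. Every simulated dataset carries one indicator column per
#' bin and exactly one of them is 1 per patient.
#'
#' @return Character vector of bin column names, youngest first.
#' @export
age_bin_names <- function() {
  lo <- seq(0L, AGE_BIN_MAX, by = AGE_BIN_WIDTH)
  c(sprintf("age_%02d_%02d", lo[-length(lo)], lo[-length(lo)] + AGE_BIN_WIDTH - 1L),
    sprintf("age_%02d_plus", AGE_BIN_MAX))
}

age_bin_mids <- function() {
  lo <- seq(0, AGE_BIN_MAX, by = AGE_BIN_WIDTH)
  mids <- lo + AGE_BIN_WIDTH / 2
  mids[length(mids)] <- AGE_BIN_MAX + AGE_BIN_WIDTH / 2
  mids
}

# one-hot age-bin matrix from continuous ages
age_to_bins <- function(age_years) {
  bins <- pmin(floor(age_years / AGE_BIN_WIDTH), AGE_BIN_MAX / AGE_BIN_WIDTH)
  nm <- age_bin_names()
  m <- matrix(0, nrow = length(age_years), ncol = length(nm),
              dimnames = list(NULL, nm))
  m[cbind(seq_along(age_years), bins + 1L)] <- 1
  m
}

# run expr with a local RNG state, restoring the caller's stream afterwards
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Define one synthetic database profile
#'
#' A profile describes how one database's population deviates from the shared
#' data-generating process: its age distribution (possibly truncated, as in a
#' commercially insured population capped at 65), its gender mix, a
#' per-feature log-odds shift of the baseline feature prevalences (case mix),
#' and a log-odds shift of the outcome model intercept (outcome-rate
#' heterogeneity). A `sample_cap` mimics drawing a fixed-size random sample
#' from a larger source population.
#'
#' @param db_id Short database name.
#' @param n_patients Number of patients to simulate (before capping).
#' @param age_mean,age_sd Mean and SD of the latent normal age distribution
#'   (years).
#' @param age_min,age_max Truncation bounds for age (years).
#' @param male_fraction Probability that a patient is male, in (0,1).
#' @param prevalence_shift Numeric vector of per-feature log-odds offsets
#'   applied to the baseline prevalences of the indicator features (recycled
#'   scalar allowed).
#' @param intercept_shift Log-odds offset added to every outcome model's
#'   intercept in this database.
#' @param sample_cap Optional positive integer; `n_patients` is truncated to
#'   this many rows.
#' @return An object of class `db_profile`.
#' @export
db_profile <- function(db_id, n_patients, age_mean, age_sd = 12,
                       age_min = 18, age_max = 100, male_fraction = 0.3,
                       prevalence_shift = 0, intercept_shift = 0,
                       sample_cap = NULL) {
  stopifnot(is.character(db_id), length(db_id) == 1L, nzchar(db_id))
  if (!is.null(sample_cap)) {
    if (!(is.numeric(sample_cap) && length(sample_cap) == 1L && sample_cap > 0))
      stop("'sample_cap' must be a positive integer or NULL")
    sample_cap <- as.integer(sample_cap)
  }
  if (n_patients < 1) stop("'n_patients' must be positive")
  if (!(male_fraction > 0 && male_fraction < 1))
    stop("'male_fraction' must lie strictly in (0,1)")
  if (!(age_min < age_max)) stop("'age_min' must be below 'age_max'")
  if (age_sd <= 0) stop("'age_sd' must be positive")
  structure(
    list(db_id = db_id, n_patients = as.integer(n_patients),
         age_mean = age_mean, age_sd = age_sd,
         age_min = age_min, age_max = age_max,
         male_fraction = male_fraction,
         prevalence_shift = prevalence_shift,
         intercept_shift = intercept_shift,
         sample_cap = sample_cap),
    class = "db_profile")
}

#' @export
print.db_profile <- function(x, ...) {
  cap <- if (is.null(x$sample_cap)) "none" else format(x$sample_cap)
  cat(sprintf(
    "<db_profile '%s'> n=%d, age ~ N(%.1f, %.1f) on [%g, %g], male %.0f%%, intercept shift %+.2f, cap %s\n",
    x$db_id, x$n_patients, x$age_mean, x$age_sd, x$age_min, x$age_max,
    100 * x$male_fraction, x$intercept_shift, cap))
  invisible(x)
}

#' Construct the shared outcome-generating model
#'
#' The ground truth holds one coefficient vector over the full design
#' (indicator features, age-bin indicators, male indicator) shared by all
#' databases and outcomes, plus one intercept per outcome. Outcome rates
#' differ across outcomes through `beta0` and across databases through each
#' profile's `intercept_shift`.
#'
#' @param feature_names Ordered names of all design columns.
#' @param baseline_prevalence Per-feature baseline probability; entries for
#'   age-bin and gender columns are implied marginals kept only to satisfy the
#'   equal-length contract (sampling of those columns is driven by the age and
#'   gender mechanisms, see `feature_type`).
#' @param beta Per-feature true log-odds coefficients.
#' @param beta0 Named numeric vector: intercept per outcome.
#' @param outcome_ids Outcome identifiers (default: names of `beta0`).
#' @param feature_type Character vector (`"indicator"`, `"age_bin"`,
#'   `"gender"`) classifying each column.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(feature_names, baseline_prevalence, beta, beta0,
                         outcome_ids = names(beta0), feature_type = NULL) {
  m <- length(feature_names)
  if (length(baseline_prevalence) != m || length(beta) != m)
    stop("feature_names, baseline_prevalence and beta must have equal length")
  if (any(baseline_prevalence <= 0 | baseline_prevalence >= 1))
    stop("baseline_prevalence entries must lie strictly in (0,1)")
  if (is.null(names(beta0))) names(beta0) <- outcome_ids
  if (is.null(feature_type)) {
    feature_type <- rep("indicator", m)
    feature_type[feature_names %in% age_bin_names()] <- "age_bin"
    feature_type[feature_names == "male"] <- "gender"
  }
  structure(
    list(feature_names = feature_names,
         baseline_prevalence = stats::setNames(baseline_prevalence, feature_names),
         beta = stats::setNames(beta, feature_names),
         beta0 = beta0,
         outcome_ids = outcome_ids,
         feature_type = feature_type),
    class = "ground_truth")
}

#' Default heterogeneous study scenario
#'
#' Builds K database profiles and a shared ground truth emulating a
#' multi-database claims study: age means spanning 35 to 75 years (for K = 5
#' the spread is 41, 35, 75, 50, 49), exactly one database whose population is
#' capped at age 65 (commercially insured), the oldest-mean database
#' restricted to ages 65 and over (Medicare-like), per-database case-mix
#' shifts on the feature prevalences, and per-database intercept shifts so
#' that the three default outcomes (rare / medium / common) span roughly
#' 0.05% to 10% across database-outcome pairs.
#'
#' @param n_databases Number of databases (>= 2; the leave-one-out design
#'   needs at least one training database plus one held out).
#' @param n_features Number of condition/drug indicator features (>= 5).
#' @param seed Integer seed; the scenario is deterministic given it.
#' @param n_patients Patients per database.
#' @param outcome_rates Named baseline outcome probabilities (at the reference
#'   case mix, zero intercept shift).
#' @return A list with elements `profiles` (list of [db_profile()]) and
#'   `truth` (a [ground_truth()]).
#' @export
default_scenario <- function(n_databases = 5, n_features = 50, seed = 1,
                             n_patients = 20000,
                             outcome_rates = c(rare = 0.0015,
                                               medium = 0.01,
                                               common = 0.05)) {
  if (n_databases < 2)
    stop("invalid scenario: need at least 2 databases (>=1 training + 1 held out)")
  if (n_features < 5) stop("invalid scenario: need at least 5 indicator features")

  # claims-network-like spread: young Medicaid-style, commercial, Medicare
  base_means <- c(41, 35, 75, 50, 49)
  age_means <- local_seed(seed, {
    if (n_databases == 2) c(35, 75)
    else if (n_databases == 3) c(35, 75, 50)
    else if (n_databases == 4) c(41, 35, 75, 50)
    else if (n_databases == 5) base_means
    else c(base_means, stats::runif(n_databases - 5, 36, 74))
  })

  # one commercially insured population capped at 65, and the Medicare-like
  # oldest population restricted to 65+
  trunc_idx <- if (any(age_means == 41)) which(age_means == 41)[1] else which.min(age_means)
  elder_idx <- which.max(age_means)
  intercept_shifts <- seq(-1, 1, length.out = n_databases)

  feat_names <- sprintf("feat_%03d", seq_len(n_features))
  all_names <- c(feat_names, age_bin_names(), "male")

  scen <- local_seed(seed + 1L, {
    base_prev <- exp(stats::runif(n_features, log(0.02), log(0.5)))
    # ~40% of indicator features carry signal
    beta_feat <- ifelse(stats::runif(n_features) < 0.4,
                        stats::rnorm(n_features, 0, 0.35), 0)
    beta_age <- 0.03 * (age_bin_mids() - 50)
    beta_male <- 0.25
    shifts <- lapply(seq_len(n_databases), function(i)
      stats::rnorm(n_features, 0, 0.4))
    list(base_prev = base_prev, beta_feat = beta_feat, beta_age = beta_age,
         beta_male = beta_male, shifts = shifts)
  })

  beta <- c(scen$beta_feat, scen$beta_age, scen$beta_male)

  # centre each outcome's intercept so the reference-population marginal rate
  # is close to the requested one (expected linear predictor at zero shift,
  # mean age 50, 30% male)
  mids <- age_bin_mids()
  ref_bin <- which.min(abs(mids - 50))
  mean_lp <- sum(scen$beta_feat * scen$base_prev) +
    scen$beta_age[ref_bin] + scen$beta_male * 0.3
  beta0 <- stats::qlogis(outcome_rates) - mean_lp
  names(beta0) <- names(outcome_rates)

  # placeholder marginals for non-sampled columns (see ground_truth docs)
  bin_prev <- rep(1 / length(age_bin_names()), length(age_bin_names()))
  truth <- ground_truth(
    feature_names = all_names,
    baseline_prevalence = c(scen$base_prev, bin_prev, 0.3),
    beta = beta, beta0 = beta0,
    outcome_ids = names(outcome_rates))

  profiles <- lapply(seq_len(n_databases), function(i) {
    db_profile(
      db_id = sprintf("db%02d", i),
      n_patients = n_patients,
      age_mean = age_means[i],
      age_sd = 12,
      age_min = if (i == elder_idx) 65 else 18,
      age_max = if (i == trunc_idx) 65 else 100,
      male_fraction = 0.3,
      prevalence_shift = scen$shifts[[i]],
      intercept_shift = intercept_shifts[i],
      sample_cap = NULL)
  })

  list(profiles = profiles, truth = truth)
}

#' Homogeneous control scenario
#'
#' Same machinery as [default_scenario()] but every database shares one
#' profile: identical age distribution, no case-mix shift and no intercept
#' shift. In this world every method's external performance should match the
#' internal benchmark up to sampling error, which makes it the null control
#' for the transportability experiment.
#'
#' @inheritParams default_scenario
#' @param outcome_rates Baseline rates; default a single common outcome.
#' @return As [default_scenario()].
#' @export
homogeneous_scenario <- function(n_databases = 5, n_features = 50, seed = 1,
                                 n_patients = 20000,
                                 outcome_rates = c(common = 0.1)) {
  scen <- default_scenario(n_databases = n_databases, n_features = n_features,
                           seed = seed, n_patients = n_patients,
                           outcome_rates = outcome_rates)
  scen$profiles <- lapply(seq_along(scen$profiles), function(i) {
    p <- scen$profiles[[i]]
    db_profile(db_id = p$db_id, n_patients = p$n_patients,
               age_mean = 50, age_sd = 12, age_min = 18, age_max = 100,
               male_fraction = p$male_fraction,
               prevalence_shift = 0, intercept_shift = 0,
               sample_cap = p$sample_cap)
  })
  scen
}

#' Simulate every database of a scenario
#'
#' Convenience wrapper: simulates each profile with a seed derived
#' deterministically from `seed` and the profile's position.
#'
#' @param scenario A list with `profiles` and `truth`, as returned by
#'   [default_scenario()] or [homogeneous_scenario()].
#' @param seed Integer base seed.
#' @return List of `labelled_dataset`s, named by db_id.
#' @export
simulate_scenario <- function(scenario, seed = 1) {
  dss <- lapply(seq_along(scenario$profiles), function(i)
    simulate_database(scenario$profiles[[i]], scenario$truth, seed = seed + i))
  names(dss) <- vapply(dss, `[[`, character(1), "db_id")
  dss
}

#' Simulate one labelled database
#'
#' Ages are drawn from a normal distribution truncated to
#' `[age_min, age_max]` (inverse-CDF sampling), indicator features are
#' Bernoulli with probability `plogis(qlogis(baseline) + prevalence_shift)`,
#' age-bin indicators are derived from the continuous ages, and each
#' outcome's labels are Bernoulli from the shared logistic model
#' `P(y = 1 | x) = plogis(beta0 + intercept_shift + x . beta)`.
#'
#' @param profile A [db_profile()].
#' @param truth A [ground_truth()].
#' @param seed Integer seed; identical inputs give byte-identical datasets.
#' @return A `labelled_dataset`: list with `db_id`, `features` (n x m 0/1
#'   matrix with column names), `age_years` (length-n numeric) and `labels`
#'   (named list of 0/1 vectors, one per outcome).
#' @export
simulate_database <- function(profile, truth, seed) {
  stopifnot(inherits(profile, "db_profile"), inherits(truth, "ground_truth"))
  if (length(truth$feature_names) == 0) stop("ground truth has no features")
  ind <- truth$feature_type == "indicator"
  n_ind <- sum(ind)
  if (n_ind == 0) stop("ground truth has no indicator features")

  n <- profile$n_patients
  if (!is.null(profile$sample_cap)) {
    if (profile$sample_cap <= 0) stop("'sample_cap' must be positive")
    n <- min(n, profile$sample_cap)
  }

  shift <- rep_len(profile$prevalence_shift, n_ind)
  p_feat <- stats::plogis(stats::qlogis(truth$baseline_prevalence[ind]) + shift)

  local_seed(seed, {
    # truncated normal ages by inverse CDF
    lo <- stats::pnorm(profile$age_min, profile$age_mean, profile$age_sd)
    hi <- stats::pnorm(profile$age_max, profile$age_mean, profile$age_sd)
    age <- stats::qnorm(stats::runif(n, lo, hi), profile$age_mean, profile$age_sd)

    x_ind <- matrix(stats::rbinom(n * n_ind, 1L, rep(p_feat, each = n)),
                    nrow = n, ncol = n_ind,
                    dimnames = list(NULL, truth$feature_names[ind]))
    x_bins <- age_to_bins(age)
    male <- matrix(stats::rbinom(n, 1L, profile$male_fraction),
                   ncol = 1, dimnames = list(NULL, "male"))
    x <- cbind(x_ind, x_bins, male)[, truth$feature_names, drop = FALSE]

    lp_base <- drop(x %*% truth$beta) + profile$intercept_shift
    labels <- lapply(truth$beta0, function(b0)
      stats::rbinom(n, 1L, stats::plogis(b0 + lp_base)))
    names(labels) <- names(truth$beta0)

    structure(
      list(db_id = profile$db_id, features = x, age_years = age,
           labels = labels),
      class = "labelled_dataset")
  })
}

#' Construct a labelled dataset by hand
#'
#' Mostly useful for toy examples and tests; [simulate_database()] is the
#' usual source of datasets.
#'
#' @param db_id Database name.
#' @param features n x m 0/1 matrix with column names.
#' @param age_years Length-n numeric vector of ages.
#' @param labels Named list of length-n 0/1 outcome vectors.
#' @return A `labelled_dataset`.
#' @export
labelled_dataset <- function(db_id, features, age_years, labels) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) stop("'features' must have column names")
  if (nrow(features) == 0) stop("'features' must have at least one row")
  if (length(age_years) != nrow(features))
    stop("'age_years' must match the feature rows")
  if (!all(features %in% c(0, 1))) stop("'features' must be 0/1")
  if (is.null(names(labels)) || !is.list(labels))
    stop("'labels' must be a named list")
  for (y in labels) {
    if (length(y) != nrow(features)) stop("labels must match the feature rows")
    if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  }
  structure(list(db_id = db_id, features = features,
                 age_years = age_years, labels = labels),
            class = "labelled_dataset")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  rates <- vapply(x$labels, mean, numeric(1))
  cat(sprintf("<labelled_dataset '%s'> %d patients, %d features, mean age %.1f\n",
              x$db_id, nrow(x$features), ncol(x$features), mean(x$age_years)))
  cat("  outcome rates:",
      paste(sprintf("%s=%.4f", names(rates), rates), collapse = ", "), "\n")
  invisible(x)
}

#' Number of patients in a labelled dataset
#' @param ds A `labelled_dataset`.
#' @return Integer row count.
#' @export
n_patients <- function(ds) nrow(ds$features)

# row subset preserving structure
subset_dataset <- function(ds, idx) {
  structure(
    list(db_id = ds$db_id,
         features = ds$features[idx, , drop = FALSE],
         age_years = ds$age_years[idx],
         labels = lapply(ds$labels, function(y) y[idx])),
    class = "labelled_dataset")
}

#' Per-feature means of a dataset
#'
#' Column means over the requested features, in the requested order. These
#' are the case-mix summaries the similarity-weighted ensemble compares: the
#' application-side vector and each model's development-side vector.
#'
#' @param ds A `labelled_dataset`.
#' @param feature_subset Non-empty character vector of column names.
#' @return Named numeric vector of means.
#' @export
population_feature_means <- function(ds, feature_subset) {
  if (length(feature_subset) == 0)
    stop("empty feature subset: cosine similarity is undefined on empty vectors")
  missing <- setdiff(feature_subset, colnames(ds$features))
  if (length(missing))
    stop("features not in dataset: ", paste(missing, collapse = ", "))
  colMeans(ds$features[, feature_subset, drop = FALSE])
}

#' Write / read a labelled dataset as CSV plus a JSON sidecar schema
#'
#' The CSV holds one row per patient (feature columns, `age_years`, one
#' `label_<outcome>` column per outcome); the sidecar records which columns
#' are features, the age column, the label columns and the database id, so a
#' round trip reconstructs the object exactly.
#'
#' @param ds A `labelled_dataset`.
#' @param path CSV file path; the sidecar is written to `<path>.schema.json`.
#' @return `write_labelled_dataset` returns `path` invisibly;
#'   `read_labelled_dataset` returns a `labelled_dataset`.
#' @export
write_labelled_dataset <- function(ds, path) {
  df <- as.data.frame(ds$features, check.names = FALSE)
  df$age_years <- ds$age_years
  for (j in names(ds$labels)) df[[paste0("label_", j)]] <- ds$labels[[j]]
  utils::write.csv(df, path, row.names = FALSE)
  schema <- list(db_id = ds$db_id,
                 feature_columns = colnames(ds$features),
                 age_column = "age_years",
                 label_columns = as.list(stats::setNames(
                   paste0("label_", names(ds$labels)), names(ds$labels))))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_labelled_dataset
#' @param path CSV file path written by [write_labelled_dataset()].
#' @export
read_labelled_dataset <- function(path) {
  schema <- jsonlite::read_json(paste0(path, ".schema.json"),
                                simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  feats <- as.matrix(df[, schema$feature_columns, drop = FALSE])
  labels <- lapply(schema$label_columns, function(col) as.integer(df[[col]]))
  structure(
    list(db_id = schema$db_id, features = feats,
         age_years = df[[schema$age_column]], labels = labels),
    class = "labelled_dataset")
}
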