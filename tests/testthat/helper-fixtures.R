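# Shared fixtures. Expensive experiment runs are computed once per test
# session and cached, so the unit files and the acceptance file can share
# them.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# the pinned default heterogeneous study run (5 dbs x 20k, 3 outcomes)
default_lodo_results <- function() {
  cached_fixture("default_lodo", {
    scen <- default_scenario(seed = 1)
    dss <- simulate_scenario(scen, seed = 1)
    suppressWarnings(run_lodo(dss, lodo_config(seed = 1)))
  })
}

# the pinned homogeneous control run (5 i.i.d. dbs x 20k, one common outcome)
homogeneous_lodo_results <- function() {
  cached_fixture("homogeneous_lodo", {
    scen <- homogeneous_scenario(seed = 1)
    dss <- simulate_scenario(scen, seed = 1)
    suppressWarnings(run_lodo(dss, lodo_config(seed = 1)))
  })
}

# a small, fast scenario for structural pipeline tests
small_datasets <- function(n_databases = 5, n = 2000, seed = 11,
                           rates = c(common = 0.1)) {
  scen <- default_scenario(n_databases = n_databases, n_features = 20,
                           seed = seed, n_patients = n,
                           outcome_rates = rates)
  simulate_scenario(scen, seed = seed)
}

# hand-built toy dataset: one informative feature, one noise feature
toy_dataset <- function(n = 400, seed = 5, rate = 0.4, db_id = "toy") {
  set.seed(seed)
  y <- rbinom(n, 1, rate)
  x <- cbind(signal = y, noise = rbinom(n, 1, 0.5))
  labelled_dataset(db_id, x, age_years = runif(n, 20, 80),
                   labels = list(out = y))
}

# minimal model card for weight/gate arithmetic tests
stub_card <- function(db_id, internal_auroc = 0.7, dev_mean_age = 50,
                      dev_feature_means = c(f1 = 0.5, f2 = 0.5),
                      coefficients = c(f1 = 1, f2 = 0.5),
                      intercept = -2, outcome_id = "out",
                      degenerate = FALSE) {
  feats <- union(names(coefficients), names(dev_feature_means))
  cf <- stats::setNames(rep(0, length(feats)), feats)
  cf[names(coefficients)] <- coefficients
  structure(
    list(db_id = db_id, outcome_id = outcome_id,
         coefficients = cf, intercept = intercept, penalty = 0.01,
         feature_names = feats,
         internal_auroc = internal_auroc,
         internal_citl = 0, internal_gradient = 1,
         dev_feature_means = dev_feature_means,
         dev_mean_age = dev_mean_age, dev_outcome_rate = 0.1,
         train_n = 100L, test_n = 25L, degenerate = degenerate),
    class = "model_card")
}
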