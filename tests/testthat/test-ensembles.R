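# Ensemble schemes: fusion weights, gating, stacking.

test_that("fusion weight formulas give the forced values", {
  cards <- list(stub_card("a", 0.75), stub_card("b", 0.65), stub_card("c", 0.55))

  w <- compute_fusion_weights("auc1", cards)
  expect_equal(unname(w$weights), c(5, 3, 1) / 9, tolerance = 1e-12)

  w2 <- compute_fusion_weights("auc2", list(stub_card("a", 0.75), stub_card("b", 0.5)))
  expect_equal(unname(w2$weights), c(0.5, 0))

  ctx <- structure(list(feature_means = c(f1 = 0.5, f2 = 0.5),
                        mean_age = 41, ages = c(41)),
                   class = "application_context")
  wa <- compute_fusion_weights("age", list(stub_card("a", dev_mean_age = 41),
                                           stub_card("b", dev_mean_age = 75)),
                               context = ctx)
  expect_equal(unname(wa$weights), c(35 / 36, 1 / 36), tolerance = 1e-12)

  wm <- compute_fusion_weights("mean", list(stub_card("a"), stub_card("b"),
                                            stub_card("c"), stub_card("d")))
  expect_equal(unname(wm$weights), rep(0.25, 4))

  # orthogonal vs identical case mix: cosine weights (1, 0)
  ctx2 <- structure(list(feature_means = c(f1 = 1, f2 = 0), mean_age = 50,
                         ages = 50), class = "application_context")
  cs <- list(
    stub_card("a", dev_feature_means = c(f1 = 1, f2 = 0),
              coefficients = c(f1 = 1, f2 = 1)),
    stub_card("b", dev_feature_means = c(f1 = 0, f2 = 1),
              coefficients = c(f1 = 1, f2 = 1)))
  ws <- compute_fusion_weights("sim", cs, context = ctx2)
  expect_equal(unname(ws$weights), c(1, 0))
})

test_that("normalized schemes sum to 1 and auc1 is permutation-equivariant", {
  ctx <- structure(list(feature_means = c(f1 = 0.4, f2 = 0.6), mean_age = 55,
                        ages = c(50, 60)), class = "application_context")
  cards <- list(stub_card("a", 0.72, 44), stub_card("b", 0.61, 71),
                stub_card("c", 0.58, 52))
  for (s in c("mean", "auc1", "sim", "age")) {
    w <- compute_fusion_weights(s, cards, context = ctx)
    expect_lt(abs(sum(w$weights) - 1), 1e-9)
    expect_true(all(w$weights >= 0))
  }
  wp <- compute_fusion_weights("auc1", cards[c(3, 1, 2)])
  w <- compute_fusion_weights("auc1", cards)
  expect_equal(wp$weights[names(w$weights)], w$weights)

  # sim weights are scale-invariant in the mean vectors (cosine property)
  ctx_scaled <- ctx
  ctx_scaled$feature_means <- 0.5 * ctx$feature_means
  cards_scaled <- lapply(cards, function(cd) {
    cd$dev_feature_means <- 0.5 * cd$dev_feature_means
    cd
  })
  expect_equal(compute_fusion_weights("sim", cards_scaled, ctx_scaled)$weights,
               compute_fusion_weights("sim", cards, ctx)$weights,
               tolerance = 1e-12)
})

test_that("degenerate weight inputs fall back or exclude as documented", {
  chance <- list(stub_card("a", 0.5), stub_card("b", 0.5))
  expect_warning(w <- compute_fusion_weights("auc1", chance), "uniform")
  expect_true(w$fallback)
  expect_equal(unname(w$weights), c(0.5, 0.5))

  ctx <- structure(list(feature_means = c(f1 = 0.4, f2 = 0.6), mean_age = 50,
                        ages = 50), class = "application_context")
  cards <- list(stub_card("a"),
                stub_card("b", degenerate = TRUE,
                          dev_feature_means = stats::setNames(numeric(0), character(0))))
  expect_warning(wd <- compute_fusion_weights("sim", cards, ctx), "degenerate")
  expect_equal(unname(wd$weights), c(1, 0))

  expect_error(compute_fusion_weights("sim", cards), "requires")
  expect_error(compute_fusion_weights("mean", cards[1]), "at least 2")
  expect_error(compute_fusion_weights("mean", list(stub_card("a"), stub_card("a"))),
               "distinct")
})

test_that("apply_fusion is the weighted sum, aligned by db_id", {
  w <- compute_fusion_weights("mean", list(stub_card("a"), stub_card("b")))
  preds <- list(a = c(0.2, 0.5), b = c(0.4, 0.7))
  expect_equal(apply_fusion(w, preds), c(0.3, 0.6))

  w$weights <- c(a = 1, b = 0)
  expect_equal(apply_fusion(w, preds), preds$a)
  # alignment is by name, not position
  expect_equal(apply_fusion(w, preds[c("b", "a")]), preds$a)

  w$weights <- c(a = 0.5, b = 0.1)
  expect_equal(apply_fusion(w, list(a = 0.9, b = 0.9)), 0.54)
  expect_error(apply_fusion(w, list(a = 0.9, z = 0.9)), "missing")

  # mean fusion of identical members is the member (identity property)
  wm <- compute_fusion_weights("mean", list(stub_card("a"), stub_card("b"),
                                            stub_card("c")))
  p <- runif(5)
  expect_equal(apply_fusion(wm, list(a = p, b = p, c = p)), p)
})

test_that("age gating is one-hot on the nearest development mean age", {
  cards <- list(stub_card("m41", dev_mean_age = 41),
                stub_card("m35", dev_mean_age = 35),
                stub_card("m75", dev_mean_age = 75),
                stub_card("m50", dev_mean_age = 50))
  g <- age_mixture_gate(cards, c(70, 50, 36))
  expect_true(all(rowSums(g) == 1))
  expect_true(all(g %in% c(0, 1)))
  expect_equal(unname(g[1, "m75"]), 1)   # |75-70| = 5 beats |50-70| = 20
  expect_equal(unname(g[2, "m50"]), 1)   # exact match
  expect_equal(unname(g[3, "m35"]), 1)

  # ties go to the lexicographically smallest db_id
  tie <- list(stub_card("zz", dev_mean_age = 50), stub_card("aa", dev_mean_age = 50))
  gt <- age_mixture_gate(tie, c(50, 80))
  expect_equal(unname(gt[, "aa"]), c(1, 1))

  # the gated prediction equals exactly one member's prediction
  preds <- list(m41 = c(0.1, 0.2, 0.3), m35 = c(0.4, 0.5, 0.6),
                m75 = c(0.7, 0.8, 0.9), m50 = c(0.15, 0.25, 0.35))
  out <- predict_age_mixture(cards, preds, c(70, 50, 36))
  expect_equal(out, c(0.7, 0.25, 0.6))

  expect_error(age_mixture_gate(cards, c(50, NA)), "missing")
})

test_that("stacking equals a direct logistic MLE on member risks", {
  dss <- small_datasets(n_databases = 3, n = 2500, seed = 31)
  cards <- lapply(dss[1:2], train_database_model, outcome_id = "common",
                  seed = 3)
  target <- dss[[3]]

  stack <- fit_stacking(cards, target, n_labels = "all", seed = 4)
  # oracle: glm on the same member risk columns
  risks <- vapply(cards, function(cd) predict_risk(cd, target),
                  numeric(n_patients(target)))
  oracle <- glm(target$labels$common ~ risks,
                family = binomial(),
                control = glm.control(epsilon = 1e-12, maxit = 100))
  expect_equal(unname(coef(stack)), unname(coef(oracle)), tolerance = 1e-8)

  # round trip: predictions reproduce the fit-time fitted values
  pred <- predict_stacking(stack, list(db01 = risks[, 1], db02 = risks[, 2]))
  expect_equal(unname(pred), unname(fitted(oracle)), tolerance = 1e-8)
  # MLE score equation: mean-calibrated on its own fitting sample
  expect_lt(abs(calibration_in_the_large(pred, target$labels$common)), 1e-8)
})

test_that("stacking edge cases: constant members, label budgets, no events", {
  dss <- small_datasets(n_databases = 3, n = 1000, seed = 37)
  target <- dss[[3]]
  r <- mean(target$labels$common)

  const <- list(stub_card("a", coefficients = c(male = 0), intercept = 0,
                          dev_feature_means = c(male = 0.3), outcome_id = "common"),
                stub_card("b", coefficients = c(male = 0), intercept = 0,
                          dev_feature_means = c(male = 0.3), outcome_id = "common"))
  st <- fit_stacking(const, target, seed = 2)
  p <- predict_stacking(st, list(a = rep(0.5, 5), b = rep(0.5, 5)))
  expect_equal(p, rep(r, 5), tolerance = 1e-9)

  st100 <- fit_stacking(const, target, n_labels = 100, seed = 6)
  expect_identical(st100$n_labels_used, 100L)
  expect_error(fit_stacking(const, target, n_labels = 1e6), "exceeds")

  # an all-zero outcome cannot be stacked: the documented failure mode
  none <- target
  none$labels$common[] <- 0
  expect_error(fit_stacking(const, none, seed = 1), "no events")
})

test_that("stacking prediction degenerate forms", {
  st <- structure(list(coefficients = c(a = 0, b = 0), intercept = 0,
                       n_labels_used = 10L, n_events = 2L, separation = FALSE,
                       use_logit = FALSE, outcome_id = "out",
                       member_ids = c("a", "b")),
                  class = "stacking_model")
  expect_equal(predict_stacking(st, list(a = c(0.1, 0.9), b = c(0.2, 0.8))),
               c(0.5, 0.5))
  st$intercept <- qlogis(0.03)
  expect_equal(predict_stacking(st, list(a = 0.4, b = 0.6)), 0.03,
               tolerance = 1e-12)
  expect_error(predict_stacking(st, list(a = 0.4)), "missing")
})
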