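# Leave-one-database-out orchestration.

test_that("the result table has one row per (fold, outcome, method)", {
  dss <- small_datasets(n_databases = 5, n = 2000, seed = 11)
  res <- suppressWarnings(run_lodo(dss, lodo_config(seed = 7)))
  # per fold: K-1 singles + 5 fusions + ageME + 3 stacking + internal benchmark
  expect_identical(nrow(res), 5L * (4L + 5L + 1L + 3L + 1L))
  expect_identical(sum(res$method == "internal_benchmark"), 5L)
  per_fold <- table(res$heldout_db)
  expect_true(all(per_fold == 14))
  # a member model never appears as a single method in its own fold
  expect_false(any(res$method == res$heldout_db))
  expect_error(run_lodo(dss[1:2]), "at least 3")
})

test_that("auroc_difference always equals the recomputed difference", {
  res <- suppressWarnings(run_lodo(small_datasets(n_databases = 3, n = 1500,
                                                  seed = 13),
                                   lodo_config(seed = 3)))
  ok <- !is.na(res$auroc_difference)
  expect_true(any(ok))
  expect_identical(res$auroc_difference[ok],
                   res$external_auroc[ok] - res$internal_benchmark_auroc[ok])
  # internal benchmark rows carry no external performance
  ib <- res[res$method == "internal_benchmark", ]
  expect_true(all(is.na(ib$external_auroc)))
  expect_true(all(!ib$skipped | !is.na(ib$skip_reason)))
})

test_that("two identical runs produce byte-identical tidy tables", {
  run_once <- function() {
    scen <- default_scenario(n_databases = 3, n_features = 15, seed = 17,
                             n_patients = 1200,
                             outcome_rates = c(common = 0.08))
    dss <- simulate_scenario(scen, seed = 17)
    suppressWarnings(run_lodo(dss, lodo_config(seed = 17)))
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  f1 <- tempfile(); f2 <- tempfile()
  on.exit(unlink(c(f1, f2, paste0(c(f1, f2), ".manifest.json"))))
  write_lodo_results(r1, f1)
  write_lodo_results(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a held-out copy of a training database matches its internal benchmark", {
  dss <- small_datasets(n_databases = 3, n = 4000, seed = 41)
  # clone the highest-event-rate database so both AUROC estimates are stable
  copy <- dss[[3]]
  copy$db_id <- "copy03"
  res <- suppressWarnings(
    run_lodo(c(dss, list(copy03 = copy)), lodo_config(seed = 5)))
  res <- as.data.frame(res)
  row <- res[res$heldout_db == "copy03" & res$method == "db03", ]
  # the db01 model evaluated on its own clone vs a model trained inside the
  # clone: the transport gap is pure sampling error
  expect_false(row$skipped)
  expect_lt(abs(row$auroc_difference), 0.08)
})

test_that("impossible cells become explicit skip rows, not silent drops", {
  dss <- small_datasets(n_databases = 3, n = 1500, seed = 43)
  # a single event: too rare to stratify a split, so no model can be trained,
  # but external evaluation inside this database still has both classes
  dss[[2]]$labels$common[] <- 0
  dss[[2]]$labels$common[1] <- 1
  res <- suppressWarnings(run_lodo(dss, lodo_config(seed = 9)))
  res <- as.data.frame(res)
  sk <- res[res$skipped, ]
  expect_gt(nrow(sk), 0)
  expect_true(all(!is.na(sk$skip_reason)))
  # db02's single-model rows and its own benchmark row are skipped
  expect_true(all(res$skipped[res$method == "db02"]))
  expect_true(res$skipped[res$method == "internal_benchmark" &
                            res$heldout_db == "db02"])
  # with only one usable member left, ensembles in other folds are skipped
  expect_true(all(res$skipped[res$method == "mean" & res$heldout_db != "db02"]))
  # ...but the fold that holds out db02 still has two members and runs
  expect_false(res$skipped[res$method == "mean" & res$heldout_db == "db02"])
})

test_that("distribution summaries are quantiles and order-invariant", {
  res <- suppressWarnings(run_lodo(small_datasets(n_databases = 3, n = 1500,
                                                  seed = 47,
                                                  rates = c(a = 0.1, b = 0.05)),
                                   lodo_config(seed = 2)))
  s <- summarize_distributions(res)
  expect_true(all(c("min", "q1", "median", "q3", "max") %in% names(s)))
  expect_true(all(s$min <= s$median & s$median <= s$max))

  shuffled <- res[sample(nrow(res)), ]
  attr(shuffled, "config") <- attr(res, "config")
  s2 <- summarize_distributions(shuffled)
  key <- function(d) d[order(d$heldout_db, d$method, d$metric),
                       c("heldout_db", "method", "metric", "min", "q1",
                         "median", "q3", "max")]
  k1 <- key(s); rownames(k1) <- NULL
  k2 <- key(s2); rownames(k2) <- NULL
  expect_equal(k1, k2)

  # one value -> all five quantiles collapse onto it
  one <- res[which(!res$skipped & res$method == "mean")[1], ]
  s1 <- summarize_distributions(one)
  ad <- s1[s1$metric == "auroc_difference", ]
  expect_equal(ad$min, ad$max)
  expect_equal(ad$median, one$auroc_difference)

  expect_error(summarize_distributions(res[0, ]), "empty")
})

test_that("headline reports stay well-formed when methods are missing", {
  res <- suppressWarnings(run_lodo(small_datasets(n_databases = 3, n = 1500,
                                                  seed = 53),
                                   lodo_config(seed = 4)))
  hr <- headline_check(res)
  expect_named(hr$flags, c("fusion_median_best", "fusion_iqr_tighter",
                           "stacking_small_budget_worse",
                           "stacking_recalibrated"))
  expect_type(hr$numbers, "list")

  # drop all stacking rows: the report flags the gap instead of erroring
  partial <- res[res$method_class != "stacking", ]
  attr(partial, "config") <- attr(res, "config")
  hr2 <- headline_check(partial)
  expect_true(is.na(hr2$flags["stacking_recalibrated"]))
  expect_gt(length(hr2$gaps), 0)
  expect_error(headline_check(res[0, ]), "empty")
})
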