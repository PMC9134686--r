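# Leave-one-database-out experiment: hold out each database in turn, train
# Level-1 models on the rest, evaluate every single model and every ensemble
# on ALL patients of the held-out database, and compare each external AUROC
# with the internal benchmark — the internal validation (20% test split) of a
# model trained inside the held-out database itself.

#' Configuration for a leave-one-database-out run
#'
#' @param outcomes Outcome ids to evaluate (default: all outcomes present in
#'   the first dataset).
#' @param test_fraction Held-out fraction for every 80/20 split.
#' @param penalty_grid Penalty grid for the Level-1 fits.
#' @param cv_folds CV folds for penalty selection.
#' @param stacking_budgets Named integer budgets for the stacking label
#'   subsamples; `NA` means all available patients.
#' @param seed Master seed; all stage seeds derive from it deterministically.
#' @param stacking_eval `"full"` evaluates the stacker on the entire held-out
#'   database including its fitting subsample (the primary behavior);
#'   `"complement"` evaluates on the patients outside the fitting subsample
#'   (leakage-aware variant).
#' @return A list of class `lodo_config`.
#' @export
lodo_config <- function(outcomes = NULL, test_fraction = 0.2,
                        penalty_grid = default_penalty_grid(),
                        cv_folds = 3,
                        stacking_budgets = c("s|1000" = 1000,
                                             "s|10000" = 10000,
                                             "s|All" = NA),
                        seed = 1,
                        stacking_eval = c("full", "complement")) {
  stacking_eval <- match.arg(stacking_eval)
  if (any(!is.na(stacking_budgets) & stacking_budgets <= 0))
    stop("stacking budgets must be positive")
  structure(
    list(outcomes = outcomes, test_fraction = test_fraction,
         penalty_grid = penalty_grid, cv_folds = cv_folds,
         stacking_budgets = stacking_budgets, seed = as.integer(seed),
         stacking_eval = stacking_eval),
    class = "lodo_config")
}

fusion_schemes <- c("mean", "auc1", "auc2", "sim", "age")

result_row <- function(heldout_db, outcome_id, method, class,
                       external_auroc = NA_real_,
                       internal_benchmark_auroc = NA_real_,
                       citl = NA_real_, gradient = NA_real_,
                       n = NA_integer_, n_events = NA_integer_,
                       skipped = FALSE, skip_reason = NA_character_) {
  data.frame(
    heldout_db = heldout_db, outcome_id = outcome_id, method = method,
    method_class = class,
    external_auroc = external_auroc,
    internal_benchmark_auroc = internal_benchmark_auroc,
    auroc_difference = external_auroc - internal_benchmark_auroc,
    citl = citl, gradient = gradient,
    n = n, n_events = n_events,
    skipped = skipped, skip_reason = skip_reason,
    stringsAsFactors = FALSE)
}

eval_predictions <- function(pred, y) {
  list(auroc = auroc(pred, y),
       citl = calibration_in_the_large(pred, y),
       gradient = tryCatch(calibration_gradient(pred, y),
                           error = function(e) NA_real_))
}

#' Run the leave-one-database-out transportability experiment
#'
#' For every held-out database `k` and outcome `j`: (1) Level-1 models are
#' trained on every other database (each database's model is fitted once per
#' outcome and reused across folds — it never depends on which database is
#' held out); (2) the internal benchmark is the internal validation of the
#' model trained inside `k` on its own 20% test split; (3) every single
#' (non-ensemble) member model, the five fusion schemes, the age-gated
#' mixture of experts and the stacking models under each label budget are
#' evaluated on ALL patients of database `k`; (4) one tidy result row per
#' (held-out database, outcome, method) is emitted. Cells that cannot be
#' computed (e.g. an event-free stacking subsample) become explicit skip rows
#' with the reason, never silent drops. The run is deterministic given the
#' config seed.
#'
#' @param datasets List of >= 3 `labelled_dataset`s with distinct db_ids.
#' @param config A [lodo_config()].
#' @return A `data.frame` of class `lodo_result`, one row per
#'   (held-out db, outcome, method), with columns `heldout_db`, `outcome_id`,
#'   `method`, `method_class` (`single` / `fusion` / `mixture` / `stacking` /
#'   `internal_benchmark`), `external_auroc`, `internal_benchmark_auroc`,
#'   `auroc_difference`, `citl`, `gradient`, `n`, `n_events`, `skipped`,
#'   `skip_reason`. The config is attached as attribute `config`.
#' @export
run_lodo <- function(datasets, config = lodo_config()) {
  if (length(datasets) < 3)
    stop("invalid design: need at least 3 databases (>= 2 ensemble members after holdout)")
  ids <- vapply(datasets, `[[`, character(1), "db_id")
  if (anyDuplicated(ids)) stop("datasets must have distinct db_ids")
  names(datasets) <- ids
  outcomes <- config$outcomes
  if (is.null(outcomes)) outcomes <- names(datasets[[1]]$labels)

  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  for (oj in seq_along(outcomes)) {
    outcome <- outcomes[oj]

    # one card per database per outcome, reused across folds
    cards <- lapply(seq_along(ids), function(i) {
      tryCatch(
        train_database_model(
          datasets[[i]], outcome,
          test_fraction = config$test_fraction,
          penalty_grid = config$penalty_grid,
          cv_folds = config$cv_folds,
          seed = config$seed + 1000L * oj + i),
        error = function(e) structure(list(message = conditionMessage(e)),
                                      class = "card_failure"))
    })
    names(cards) <- ids

    for (k in seq_along(ids)) {
      held_id <- ids[k]
      ds_k <- datasets[[k]]
      y_k <- ds_k$labels[[outcome]]
      n_k <- n_patients(ds_k)
      n_ev <- sum(y_k == 1)

      bench <- cards[[k]]
      bench_ok <- inherits(bench, "model_card")
      internal <- if (bench_ok) bench$internal_auroc else NA_real_

      add(result_row(
        held_id, outcome, "internal_benchmark", "internal_benchmark",
        external_auroc = NA_real_, internal_benchmark_auroc = internal,
        citl = if (bench_ok) bench$internal_citl else NA_real_,
        gradient = if (bench_ok) bench$internal_gradient else NA_real_,
        n = if (bench_ok) bench$test_n else NA_integer_,
        n_events = n_ev,
        skipped = !bench_ok,
        skip_reason = if (bench_ok) NA_character_ else bench$message))

      members <- cards[ids != held_id]
      ok <- vapply(members, inherits, logical(1), "model_card")

      # single (non-ensemble) member models
      for (i in which(!ok))
        add(result_row(held_id, outcome, names(members)[i], "single",
                       internal_benchmark_auroc = internal,
                       n = n_k, n_events = n_ev, skipped = TRUE,
                       skip_reason = members[[i]]$message))
      members <- members[ok]
      member_preds <- NULL
      if (length(members) > 0) {
        member_preds <- vapply(members, function(card)
          predict_risk(card, ds_k), numeric(n_k))
        colnames(member_preds) <- names(members)
        for (i in seq_along(members)) {
          ev <- tryCatch(eval_predictions(member_preds[, i], y_k),
                         error = function(e) e)
          if (inherits(ev, "error"))
            add(result_row(held_id, outcome, names(members)[i], "single",
                           internal_benchmark_auroc = internal,
                           n = n_k, n_events = n_ev, skipped = TRUE,
                           skip_reason = conditionMessage(ev)))
          else
            add(result_row(held_id, outcome, names(members)[i], "single",
                           external_auroc = ev$auroc,
                           internal_benchmark_auroc = internal,
                           citl = ev$citl, gradient = ev$gradient,
                           n = n_k, n_events = n_ev))
        }
      }

      enough <- length(members) >= 2
      ens_skip <- function(method, cls, reason)
        add(result_row(held_id, outcome, method, cls,
                       internal_benchmark_auroc = internal,
                       n = n_k, n_events = n_ev,
                       skipped = TRUE, skip_reason = reason))

      if (!enough) {
        for (s in fusion_schemes) ens_skip(s, "fusion", "fewer than 2 usable member models")
        ens_skip("ageME", "mixture", "fewer than 2 usable member models")
        for (b in names(config$stacking_budgets))
          ens_skip(b, "stacking", "fewer than 2 usable member models")
        next
      }

      ctx <- application_context(ds_k)

      for (s in fusion_schemes) {
        res <- tryCatch({
          w <- withCallingHandlers(
            compute_fusion_weights(s, members, ctx),
            warning = function(w) invokeRestart("muffleWarning"))
          eval_predictions(apply_fusion(w, member_preds), y_k)
        }, error = function(e) e)
        if (inherits(res, "error")) ens_skip(s, "fusion", conditionMessage(res))
        else add(result_row(held_id, outcome, s, "fusion",
                            external_auroc = res$auroc,
                            internal_benchmark_auroc = internal,
                            citl = res$citl, gradient = res$gradient,
                            n = n_k, n_events = n_ev))
      }

      res <- tryCatch(
        eval_predictions(
          predict_age_mixture(members, member_preds, ds_k$age_years), y_k),
        error = function(e) e)
      if (inherits(res, "error")) ens_skip("ageME", "mixture", conditionMessage(res))
      else add(result_row(held_id, outcome, "ageME", "mixture",
                          external_auroc = res$auroc,
                          internal_benchmark_auroc = internal,
                          citl = res$citl, gradient = res$gradient,
                          n = n_k, n_events = n_ev))

      for (b in seq_along(config$stacking_budgets)) {
        bname <- names(config$stacking_budgets)[b]
        budget <- config$stacking_budgets[b]
        n_lab <- if (is.na(budget)) n_k else as.integer(budget)
        if (n_lab > n_k) {
          warning("stacking budget ", bname, " exceeds held-out size; clipped to ", n_k)
          n_lab <- n_k
        }
        res <- tryCatch({
          stack <- withCallingHandlers(
            fit_stacking(members, ds_k, n_labels = n_lab,
                         seed = config$seed + 1000L * oj + 100L * k + b),
            warning = function(w) invokeRestart("muffleWarning"))
          eval_idx <- seq_len(n_k)
          if (config$stacking_eval == "complement") {
            fit_idx <- local_seed(config$seed + 1000L * oj + 100L * k + b,
                                  sample.int(n_k, n_lab))
            eval_idx <- setdiff(eval_idx, fit_idx)
            if (length(eval_idx) == 0) stop("no patients left outside the fitting subsample")
          }
          pred <- predict_stacking(stack, member_preds[eval_idx, , drop = FALSE])
          eval_predictions(pred, y_k[eval_idx])
        }, error = function(e) e)
        if (inherits(res, "error")) ens_skip(bname, "stacking", conditionMessage(res))
        else add(result_row(held_id, outcome, bname, "stacking",
                            external_auroc = res$auroc,
                            internal_benchmark_auroc = internal,
                            citl = res$citl, gradient = res$gradient,
                            n = n_k, n_events = n_ev))
      }
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("lodo_result", class(out))
  out
}

#' @export
print.lodo_result <- function(x, ...) {
  cat(sprintf(
    "<lodo_result> %d rows: %d held-out databases x %d outcomes x %d methods (%d skipped)\n",
    nrow(x), length(unique(x$heldout_db)), length(unique(x$outcome_id)),
    length(unique(x$method)), sum(x$skipped)))
  invisible(x)
}

#' Five-number summaries of the transport metrics
#'
#' Per (held-out database, method): min, first quartile, median, third
#' quartile and max of `auroc_difference`, `citl` and `gradient` over
#' outcomes — the numbers a transportability boxplot panel displays.
#' Skipped rows are excluded.
#'
#' @param results A `lodo_result`.
#' @return A `data.frame` with one row per (held-out db, method, metric).
#' @export
summarize_distributions <- function(results) {
  stopifnot(inherits(results, "lodo_result") || is.data.frame(results))
  if (nrow(results) == 0) stop("empty results")
  ok <- results[!results$skipped, , drop = FALSE]
  metrics <- c("auroc_difference", "citl", "gradient")
  groups <- unique(ok[, c("heldout_db", "method", "method_class")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sel <- ok$heldout_db == groups$heldout_db[g] & ok$method == groups$method[g]
    do.call(rbind, lapply(metrics, function(m) {
      v <- ok[[m]][sel]
      v <- v[!is.na(v)]
      if (length(v) == 0) return(NULL)
      q <- unname(stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1)))
      data.frame(heldout_db = groups$heldout_db[g],
                 method = groups$method[g],
                 method_class = groups$method_class[g],
                 metric = m, n = length(v),
                 min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' @export
summary.lodo_result <- function(object, ...) summarize_distributions(object)

pooled_stats <- function(results, method, metric = "auroc_difference",
                         outcomes = NULL) {
  sel <- !results$skipped & results$method == method &
    !is.na(results[[metric]])
  if (!is.null(outcomes)) sel <- sel & results$outcome_id %in% outcomes
  results[[metric]][sel]
}

#' Check the experiment's qualitative headline findings
#'
#' Computes four boolean flags with their supporting numbers, pooling over
#' held-out databases and outcomes:
#' \describe{
#'   \item{fusion_median_best}{the mean-fusion median `auroc_difference` is at
#'     least every single-database method's median (fusion transports at
#'     least as well as any one model).}
#'   \item{fusion_iqr_tighter}{the mean-fusion IQR of `auroc_difference` is no
#'     larger than the IQR pooled over all single-database methods (fusion is
#'     more consistent).}
#'   \item{stacking_small_budget_worse}{on the rare outcome(s), the s|1000
#'     median `auroc_difference` does not exceed the mean-fusion median
#'     (stacking degrades when labels are scarce).}
#'   \item{stacking_recalibrated}{the median |calibration-in-the-large| of
#'     s|All is no larger than that of every fusion scheme (stacking with all
#'     labels is effectively recalibrated).}
#' }
#' Flags are reported, not asserted; methods missing from the results yield
#' explicit `NA` flags with a gap note.
#'
#' @param results A `lodo_result`.
#' @param rare_outcomes Outcome ids counted as rare; default the outcome with
#'   the lowest pooled event rate.
#' @return An object of class `headline_report`.
#' @export
headline_check <- function(results, rare_outcomes = NULL) {
  if (nrow(results) == 0) stop("empty results")
  singles <- unique(results$method[results$method_class == "single"])
  gaps <- character(0)

  if (is.null(rare_outcomes)) {
    ev <- tapply(results$n_events / results$n, results$outcome_id, mean,
                 na.rm = TRUE)
    rare_outcomes <- names(ev)[which.min(ev)]
  }

  med <- function(v) if (length(v)) stats::median(v) else NA_real_
  iqr <- function(v) if (length(v)) stats::IQR(v) else NA_real_

  mean_med <- med(pooled_stats(results, "mean"))
  single_meds <- vapply(singles, function(s)
    med(pooled_stats(results, s)), numeric(1))
  if (!length(singles)) gaps <- c(gaps, "no single-model rows")
  a <- if (length(singles) && !is.na(mean_med) && !anyNA(single_meds))
    mean_med >= max(single_meds) else NA

  mean_iqr <- iqr(pooled_stats(results, "mean"))
  single_pool <- unlist(lapply(singles, function(s) pooled_stats(results, s)))
  b <- if (length(single_pool) && !is.na(mean_iqr))
    mean_iqr <= iqr(single_pool) else NA

  s1000_rare <- med(pooled_stats(results, "s|1000", outcomes = rare_outcomes))
  mean_rare <- med(pooled_stats(results, "mean", outcomes = rare_outcomes))
  if (is.na(s1000_rare)) gaps <- c(gaps, "no usable s|1000 rows on the rare outcome(s)")
  cc <- if (!is.na(s1000_rare) && !is.na(mean_rare)) s1000_rare <= mean_rare else NA

  sall_citl <- med(abs(pooled_stats(results, "s|All", metric = "citl")))
  fusion_citl <- vapply(fusion_schemes, function(s)
    med(abs(pooled_stats(results, s, metric = "citl"))), numeric(1))
  if (is.na(sall_citl)) gaps <- c(gaps, "no usable s|All rows")
  d <- if (!is.na(sall_citl) && !anyNA(fusion_citl))
    sall_citl <= min(fusion_citl) else NA

  structure(
    list(flags = c(fusion_median_best = a,
                   fusion_iqr_tighter = b,
                   stacking_small_budget_worse = cc,
                   stacking_recalibrated = d),
         numbers = list(
           mean_fusion_median = mean_med,
           single_model_medians = single_meds,
           mean_fusion_iqr = mean_iqr,
           pooled_single_iqr = iqr(single_pool),
           rare_outcomes = rare_outcomes,
           s1000_rare_median = s1000_rare,
           mean_fusion_rare_median = mean_rare,
           sAll_median_abs_citl = sall_citl,
           fusion_median_abs_citl = fusion_citl),
         gaps = gaps),
    class = "headline_report")
}

#' @export
print.headline_report <- function(x, ...) {
  cat("<headline_report>\n")
  for (nm in names(x$flags))
    cat(sprintf("  %-28s %s\n", nm,
                if (is.na(x$flags[nm])) "NA" else as.character(x$flags[nm])))
  if (length(x$gaps)) cat("  gaps:", paste(x$gaps, collapse = "; "), "\n")
  invisible(x)
}

#' Boxplots of a transport metric by method
#'
#' One box per method (ordered single models, fusion, mixture, stacking),
#' pooled over held-out databases and outcomes; the dashed line marks the
#' perfect-transport reference (0 for `auroc_difference` and `citl`, 1 for
#' `gradient`).
#'
#' @param x A `lodo_result`.
#' @param metric One of `"auroc_difference"`, `"citl"`, `"gradient"`.
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, the boxplot stats.
#' @export
plot.lodo_result <- function(x, metric = c("auroc_difference", "citl", "gradient"),
                             ...) {
  metric <- match.arg(metric)
  ok <- x[!x$skipped & x$method_class != "internal_benchmark" &
            !is.na(x[[metric]]), , drop = FALSE]
  cls_order <- c("single", "fusion", "mixture", "stacking")
  meths <- unique(ok[order(match(ok$method_class, cls_order), ok$method),
                     "method"])
  ok$method <- factor(ok$method, levels = meths)
  bp <- graphics::boxplot(ok[[metric]] ~ ok$method, las = 2,
                          xlab = "", ylab = metric, ...)
  graphics::abline(h = if (metric == "gradient") 1 else 0, lty = 2)
  invisible(bp)
}

#' Write tidy results and a run manifest
#'
#' The result table goes to `<path>` as CSV; the manifest (config and package
#' version) to `<path>.manifest.json`.
#'
#' @param results A `lodo_result`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_lodo_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  cfg <- attr(results, "config")
  manifest <- list(
    package = "dbEnsembles",
    version = as.character(utils::packageVersion("dbEnsembles")),
    config = list(
      outcomes = cfg$outcomes, test_fraction = cfg$test_fraction,
      penalty_grid = cfg$penalty_grid, cv_folds = cfg$cv_folds,
      stacking_budgets = as.list(cfg$stacking_budgets),
      seed = cfg$seed, stacking_eval = cfg$stacking_eval))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
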