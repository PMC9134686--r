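# Discrimination and calibration metrics.
#
# AUROC is the probability that a randomly sampled outcome patient receives a
# higher predicted risk than a randomly sampled non-outcome patient; ties
# count 0.5.  Predictions are allowed outside [0,1] because the unnormalized
# AUROC-weighted fusion can produce such values and they are evaluated as-is.

check_scored <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  if (length(labels) == 0) stop("empty input")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  invisible(TRUE)
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney estimate: average ranks of the outcome patients' predictions,
#' so tied prediction pairs contribute 0.5.
#'
#' @param predictions Numeric risk scores (need not lie in \[0,1\]).
#' @param labels 0/1 outcome labels, at least one of each class.
#' @return AUROC in \[0,1\].
#' @export
auroc <- function(predictions, labels) {
  check_scored(predictions, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("undefined AUROC: labels contain a single class")
  r <- rank(predictions)   # average ranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Exhaustive pairwise AUROC (testing oracle)
#'
#' Literal implementation of the definition: the mean over all
#' (outcome, non-outcome) pairs of `1[p_case > p_control] + 0.5 * 1[equal]`.
#' Quadratic in n; guarded at n <= 10000. Kept independent of [auroc()] so it
#' can serve as its oracle.
#'
#' @inheritParams auroc
#' @return AUROC in \[0,1\].
#' @export
auroc_pairwise_oracle <- function(predictions, labels) {
  check_scored(predictions, labels)
  if (length(labels) > 10000) stop("pairwise oracle limited to n <= 10000")
  p1 <- predictions[labels == 1]
  p0 <- predictions[labels == 0]
  if (length(p1) == 0 || length(p0) == 0)
    stop("undefined AUROC: labels contain a single class")
  cmp <- outer(p1, p0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

#' Calibration-in-the-large
#'
#' Observed event rate minus mean predicted risk; 0 indicates mean-level
#' agreement between predictions and outcomes.
#'
#' @inheritParams auroc
#' @return A scalar (positive when the model under-predicts risk).
#' @export
calibration_in_the_large <- function(predictions, labels) {
  check_scored(predictions, labels)
  mean(labels) - mean(predictions)
}

#' Calibration gradient (slope)
#'
#' Patients are sorted by predicted risk into `n_bins` equal-count quantile
#' bins; within each bin the mean prediction and the observed event fraction
#' are computed, and the gradient is the ordinary least-squares slope of
#' observed fraction on mean prediction across bins. A slope near 1 indicates
#' the spread of the predictions matches the spread of the observed risk;
#' slopes far above 1 indicate the model systematically predicts risks that
#' are too small (compressed toward zero). When n is small the bin count is
#' reduced to
#' `floor(n / 2)` (at least 2) so every bin holds at least two patients.
#'
#' @inheritParams auroc
#' @param n_bins Number of quantile bins (default 100).
#' @return The OLS slope.
#' @export
calibration_gradient <- function(predictions, labels, n_bins = 100) {
  check_scored(predictions, labels)
  if (n_bins < 2) stop("'n_bins' must be at least 2")
  n <- length(labels)
  n_bins <- max(2L, min(as.integer(n_bins), n %/% 2L))
  bin <- ceiling(seq_len(n) / n * n_bins)[rank(predictions, ties.method = "first")]
  mp <- tapply(predictions, bin, mean)
  of <- tapply(labels, bin, mean)
  if (stats::var(mp) == 0)
    stop("undefined calibration slope: binned mean predictions have zero variance")
  unname(stats::cov(mp, of) / stats::var(mp))
}

#' Transportability gap in discrimination
#'
#' External-validation AUROC minus the internal benchmark AUROC (the internal
#' validation of a model trained inside the evaluation database). Values near
#' 0 mean the transported model matches what a locally trained model achieves.
#'
#' @param external_auroc,internal_auroc AUROC values in \[0,1\].
#' @return `external_auroc - internal_auroc`.
#' @export
auroc_difference <- function(external_auroc, internal_auroc) {
  stopifnot(all(external_auroc >= 0 & external_auroc <= 1, na.rm = TRUE),
            all(internal_auroc >= 0 & internal_auroc <= 1, na.rm = TRUE))
  external_auroc - internal_auroc
}
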