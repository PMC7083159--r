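# Positive class throughout: "abnormal". True labels are supplied either
# as "abnormal"/"normal" strings or as 0/1 with 1 = abnormal.

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    l <- as.character(labels)
    if (!all(l %in% c("abnormal", "normal")))
      stop('labels must be "abnormal"/"normal" or 0/1')
    as.integer(l == "abnormal")
  } else {
    l <- as.integer(labels)
    if (!all(l %in% c(0L, 1L))) stop("numeric labels must be 0/1")
    l
  }
}

#' Confusion counts at a probability threshold
#'
#' @param labels_true Truth labels (`"abnormal"`/`"normal"` or 0/1 with
#'   1 = abnormal, the positive class).
#' @param p_abnormal Predicted abnormal-class probabilities.
#' @param threshold Decision threshold: predicted abnormal when
#'   `p_abnormal >= threshold` (default 0.5).
#' @return A list of class `confusion_counts` with fields `tp, fp, tn, fn`.
#' @export
confusion <- function(labels_true, p_abnormal, threshold = 0.5) {
  y <- as_binary_labels(labels_true)
  if (length(y) == 0L) stop("empty input")
  if (length(y) != length(p_abnormal)) stop("length mismatch")
  pred <- as.integer(p_abnormal >= threshold)
  structure(list(tp = sum(pred == 1 & y == 1), fp = sum(pred == 1 & y == 0),
                 tn = sum(pred == 0 & y == 0), fn = sum(pred == 0 & y == 1)),
            class = "confusion_counts")
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC swept over the unique score values (plus
#' the degenerate all-positive / all-negative endpoints). Invariant under
#' strictly monotone transforms of the scores.
#'
#' @inheritParams confusion
#' @return AUC in `[0, 1]`, or `NA` if either class is absent.
#' @export
roc_auc <- function(labels_true, p_abnormal) {
  y <- as_binary_labels(labels_true)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  cuts <- c(Inf, sort(unique(p_abnormal), decreasing = TRUE), -Inf)
  tpr <- vapply(cuts, function(t) sum(p_abnormal >= t & y == 1) / n_pos, numeric(1))
  fpr <- vapply(cuts, function(t) sum(p_abnormal >= t & y == 0) / n_neg, numeric(1))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Classification metric suite
#'
#' Accuracy, AUC, sensitivity, specificity, F measure and Matthews
#' correlation coefficient (MCC) from confusion counts and raw scores:
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`,
#' `F = 2tp/(2tp+fp+fn)`,
#' `MCC = (tp*tn - fp*fn)/sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.
#' Degenerate cells follow the usual conventions: a metric whose defining
#' class is empty is `NA`; an MCC with a zero denominator is 0.
#'
#' @param cc A [confusion()] result.
#' @param labels_true,p_abnormal Passed through to [roc_auc()]; omit both
#'   to skip the AUC.
#' @return A list with fields `accuracy, auc, sensitivity, specificity,
#'   f_measure, mcc, n`.
#' @export
metric_suite <- function(cc, labels_true = NULL, p_abnormal = NULL) {
  stopifnot(inherits(cc, "confusion_counts"))
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  n <- tp + fp + tn + fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  auc <- if (is.null(labels_true)) NA_real_ else roc_auc(labels_true, p_abnormal)
  list(accuracy = (tp + tn) / n, auc = auc, sensitivity = sens,
       specificity = spec, f_measure = f, mcc = mcc, n = n)
}

#' Wilson score confidence interval for a proportion
#'
#' The Wilson interval for an observed proportion `p_hat` out of `n`
#' trials, at two-sided coverage `coverage` (so
#' `z = qnorm(1 - (1 - coverage)/2)`). For simultaneous statements about
#' two intervals at family coverage 0.95, each is computed at individual
#' coverage `sqrt(0.95)`.
#'
#' The interval always contains `p_hat` and stays within `[0, 1]`; it is
#' also applied, as in the source study, to AUC values treated as
#' proportions with `n` the test-set size — a pragmatic convention, since
#' an AUC is not a binomial proportion.
#'
#' @param p_hat Observed proportion in `[0, 1]`.
#' @param n Number of trials (>= 1).
#' @param coverage Two-sided coverage probability in (0, 1); default 0.95.
#' @return Numeric `c(low, high)`.
#' @export
wilson_interval <- function(p_hat, n, coverage = 0.95) {
  if (p_hat < 0 || p_hat > 1) stop("p_hat must lie in [0, 1]")
  if (n < 1) stop("n must be at least 1")
  if (coverage <= 0 || coverage >= 1) stop("coverage must lie in (0, 1)")
  z <- stats::qnorm(1 - (1 - coverage) / 2)
  denom <- 1 + z^2 / n
  center <- (p_hat + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2))
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Metric suite plus Wilson interval for the AUC, JSON-ready
#'
#' @inheritParams confusion
#' @param coverage Per-interval coverage for the AUC interval; the default
#'   `sqrt(0.95)` yields simultaneous two-sided 95% statements.
#' @return A list `{accuracy, auc, auc_ci, sensitivity, specificity,
#'   f_measure, mcc, n}`.
#' @export
evaluate_classifier <- function(labels_true, p_abnormal, threshold = 0.5,
                                coverage = sqrt(0.95)) {
  cc <- confusion(labels_true, p_abnormal, threshold)
  ms <- metric_suite(cc, labels_true, p_abnormal)
  ms$auc_ci <- if (is.na(ms$auc)) c(NA_real_, NA_real_) else
    unname(wilson_interval(ms$auc, ms$n, coverage))
  ms[c("accuracy", "auc", "auc_ci", "sensitivity", "specificity",
       "f_measure", "mcc", "n")]
}
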