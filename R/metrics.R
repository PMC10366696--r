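# Core performance statistics: discrimination (AUROC via rank-sum, average
# precision via the recall-increment step sum), confusion-matrix operating
# points with Wilson intervals, alert burden (NNE), and binned calibration.
# The positive-classification convention everywhere is score >= threshold.

#' Area under the ROC curve (rank-sum estimator)
#'
#' The probability that a randomly chosen positive unit outranks a randomly
#' chosen negative unit, with ties counting one half:
#' `(concordant + 0.5 * tied) / (n_pos * n_neg)`. Computed from the rank sum
#' of positives in O(n log n).
#'
#' @param labels Binary vector (0/1 or logical).
#' @param scores Numeric scores, higher = higher risk.
#' @return AUROC in \[0,1\].
#' @examples
#' auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)) # 0.75
#' @export
auroc <- function(labels, scores) {
  labels <- check_binary_labels(labels)
  if (length(labels) != length(scores)) abort_metric("labels/scores length mismatch")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0) abort_metric("AUROC undefined: no positive labels")
  if (n_neg == 0) abort_metric("AUROC undefined: no negative labels")
  r <- rank(scores, ties.method = "average")
  n_pos <- as.double(n_pos)
  n_neg <- as.double(n_neg)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision (area under the precision-recall curve)
#'
#' The recall-increment-weighted mean of precision across descending unique
#' score thresholds: `sum over thresholds of (recall_t - recall_{t-1}) *
#' precision_t`. Equals the prevalence exactly when all scores are tied.
#'
#' @inheritParams auroc
#' @return Average precision in (0, 1\].
#' @export
average_precision <- function(labels, scores) {
  labels <- check_binary_labels(labels)
  if (length(labels) != length(scores)) abort_metric("labels/scores length mismatch")
  n_pos <- sum(labels == 1)
  if (n_pos == 0) abort_metric("average precision undefined: no positive labels")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  cum_tp <- cumsum(y)
  # last index of each tied block = a unique threshold
  idx <- which(c(s[-1] != s[-length(s)], TRUE))
  precision <- cum_tp[idx] / idx
  recall <- cum_tp[idx] / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes Number of successes.
#' @param n Number of trials (must be positive).
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' wilson_interval(8, 10) # (0.490, 0.943)
#' @export
wilson_interval <- function(successes, n, level = 0.95) {
  if (length(n) != 1 || n <= 0) abort_validation("n must be a single positive count")
  if (successes < 0 || successes > n) abort_validation("successes must lie in [0, n]")
  z <- stats::qnorm((1 + level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' F1 score from sensitivity and positive predictive value
#'
#' Harmonic mean `2 s p / (s + p)`; defined as 0 when both inputs are 0.
#'
#' @param sensitivity,ppv Proportions in \[0,1\].
#' @return F1 in \[0,1\].
#' @export
f1_score <- function(sensitivity, ppv) {
  if (any(sensitivity < 0 | sensitivity > 1, na.rm = TRUE) ||
      any(ppv < 0 | ppv > 1, na.rm = TRUE)) {
    abort_validation("sensitivity and ppv must lie in [0,1]")
  }
  out <- ifelse(sensitivity + ppv == 0, 0,
                2 * sensitivity * ppv / (sensitivity + ppv))
  out
}

#' Number needed to evaluate
#'
#' The reciprocal of the positive predictive value: how many flagged
#' predictions must be reviewed to find one true positive. A confidence
#' interval is obtained by inverting the PPV interval and swapping its
#' endpoints.
#'
#' @param ppv Positive predictive value (> 0); `NA` or 0 yields `NA` with a
#'   warning (absent, never infinity).
#' @param ppv_interval Optional `c(lower, upper)` interval for the PPV.
#' @return NNE (numeric), with attribute `interval` when requested.
#' @examples
#' nne(0.021) # 47.6...
#' @export
nne <- function(ppv, ppv_interval = NULL) {
  if (is.na(ppv) || ppv <= 0) {
    rlang::warn("NNE undefined for PPV of 0; returning NA")
    return(NA_real_)
  }
  out <- 1 / ppv
  if (!is.null(ppv_interval)) {
    attr(out, "interval") <- c(lower = 1 / ppv_interval[[2]],
                               upper = 1 / ppv_interval[[1]])
  }
  out
}

prop_ci <- function(successes, n, level) {
  if (n == 0) return(c(est = NA_real_, lower = NA_real_, upper = NA_real_))
  w <- wilson_interval(successes, n, level)
  c(est = successes / n, lower = w[["lower"]], upper = w[["upper"]])
}

#' Operating point of a score threshold
#'
#' Classifies `score >= threshold` as positive and reports the full confusion
#' matrix with sensitivity, specificity, PPV, NPV (Wilson intervals), F1 and
#' NNE. When nothing is flagged (`tp + fp = 0`) the PPV and NNE are reported
#' as absent with `ppv_defined = FALSE`, never as zero or infinity. An
#' F1 interval can be added by percentile bootstrap.
#'
#' @inheritParams auroc
#' @param threshold Score threshold.
#' @param level Confidence level for Wilson intervals.
#' @param boot_f1 If `TRUE`, bootstrap a percentile interval for F1.
#' @param B,seed Bootstrap replicates and seed (used when `boot_f1 = TRUE`).
#' @return A `dti_operating_point` list: `threshold`, counts `tp fp tn fn`,
#'   and `c(est, lower, upper)` vectors `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `f1`, `nne`, plus flags.
#' @export
operating_point <- function(labels, scores, threshold, level = 0.95,
                            boot_f1 = FALSE, B = 500, seed = NULL) {
  labels <- check_binary_labels(labels)
  if (length(labels) != length(scores)) abort_metric("labels/scores length mismatch")
  flag <- scores >= threshold
  tp <- sum(flag & labels == 1)
  fp <- sum(flag & labels == 0)
  fn <- sum(!flag & labels == 1)
  tn <- sum(!flag & labels == 0)

  sens <- prop_ci(tp, tp + fn, level)
  spec <- prop_ci(tn, tn + fp, level)
  npv <- prop_ci(tn, tn + fn, level)
  ppv_defined <- (tp + fp) > 0
  ppv <- if (ppv_defined) prop_ci(tp, tp + fp, level) else
    c(est = NA_real_, lower = NA_real_, upper = NA_real_)

  f1 <- if (ppv_defined && !is.na(sens[["est"]])) {
    f1_score(sens[["est"]], ppv[["est"]])
  } else NA_real_
  f1v <- c(est = f1, lower = NA_real_, upper = NA_real_)
  if (boot_f1 && !is.na(f1)) {
    ci <- bootstrap_interval(
      function(l, s) {
        fl <- s >= threshold
        tp_ <- sum(fl & l == 1); fp_ <- sum(fl & l == 0); fn_ <- sum(!fl & l == 1)
        if (tp_ + fp_ == 0 || tp_ + fn_ == 0) stop("degenerate replicate")
        f1_score(tp_ / (tp_ + fn_), tp_ / (tp_ + fp_))
      },
      labels, scores, B = B, seed = seed, level = level
    )
    f1v <- c(est = f1, lower = ci[["lower"]], upper = ci[["upper"]])
  }

  nne_v <- c(est = NA_real_, lower = NA_real_, upper = NA_real_)
  if (ppv_defined && ppv[["est"]] > 0) {
    nne_v <- c(est = 1 / ppv[["est"]],
               lower = 1 / ppv[["upper"]], upper = 1 / ppv[["lower"]])
  }

  structure(
    list(
      threshold = threshold,
      tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
      f1 = f1v, nne = nne_v,
      ppv_defined = ppv_defined, level = level
    ),
    class = "dti_operating_point"
  )
}

#' @export
print.dti_operating_point <- function(x, ...) {
  cat(sprintf("<operating point at threshold %.4g>\n", x$threshold))
  cat(sprintf("  tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  fmt <- function(v, name) {
    if (is.na(v[["est"]])) return(sprintf("  %-12s absent\n", name))
    sprintf("  %-12s %.3f (%.3f-%.3f)\n", name, v[["est"]], v[["lower"]], v[["upper"]])
  }
  cat(fmt(x$sensitivity, "sensitivity"))
  cat(fmt(x$specificity, "specificity"))
  cat(fmt(x$ppv, "ppv"))
  cat(fmt(x$npv, "npv"))
  cat(fmt(x$f1, "f1"))
  cat(fmt(x$nne, "nne"))
  invisible(x)
}

#' ROC / precision-recall curve points at every observed threshold
#'
#' @inheritParams auroc
#' @return Tibble in descending threshold order: `threshold`, `tp`, `fp`,
#'   `sensitivity`, `fpr` (one minus specificity), `precision`.
#' @export
curve_points <- function(labels, scores) {
  labels <- check_binary_labels(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  idx <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[idx]
  fp <- idx - tp
  tibble::tibble(
    threshold = s[idx],
    tp = tp, fp = fp,
    sensitivity = if (n_pos > 0) tp / n_pos else NA_real_,
    fpr = if (n_neg > 0) fp / n_neg else NA_real_,
    precision = tp / idx
  )
}

#' Discrimination summary (AUROC + average precision) with optional bootstrap CIs
#'
#' @inheritParams auroc
#' @param ci Compute percentile-bootstrap intervals?
#' @param B,seed,level Bootstrap replicates, seed, confidence level.
#' @param cluster Optional cluster key (e.g. encounter id) for cluster
#'   bootstrap, respecting within-encounter correlation of observations.
#' @return A `dti_curve_metrics` list: `auroc`, `auroc_ci`, `auprc`,
#'   `auprc_ci`, `n_pos`, `n_neg`, `curve_points`.
#' @export
curve_metrics <- function(labels, scores, ci = FALSE, B = 1000, seed = NULL,
                          level = 0.95, cluster = NULL) {
  a <- auroc(labels, scores)
  ap <- average_precision(labels, scores)
  a_ci <- ap_ci <- c(lower = NA_real_, upper = NA_real_)
  if (ci) {
    a_ci <- bootstrap_interval(auroc, labels, scores, B = B, seed = seed,
                               level = level, cluster = cluster)
    ap_seed <- if (is.null(seed)) NULL else seed + 1
    ap_ci <- bootstrap_interval(average_precision, labels, scores, B = B,
                                seed = ap_seed, level = level, cluster = cluster)
  }
  structure(
    list(auroc = a, auroc_ci = a_ci, auprc = ap, auprc_ci = ap_ci,
         n_pos = sum(check_binary_labels(labels) == 1),
         n_neg = sum(check_binary_labels(labels) == 0),
         curve_points = curve_points(labels, scores)),
    class = "dti_curve_metrics"
  )
}

#' @export
print.dti_curve_metrics <- function(x, ...) {
  cat(sprintf("<curve metrics> n_pos=%d n_neg=%d\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUROC %.3f (%.3f-%.3f)\n", x$auroc,
              x$auroc_ci[["lower"]], x$auroc_ci[["upper"]]))
  cat(sprintf("  AUPRC %.3f (%.3f-%.3f)\n", x$auprc,
              x$auprc_ci[["lower"]], x$auprc_ci[["upper"]]))
  invisible(x)
}

#' Binned calibration table
#'
#' Partitions predicted risk (score/100) into `n_bins` equal-width bins on
#' \[0,1\] — right-open except the last bin, which is closed so a risk of
#' exactly 1 lands in the final bin — and reports per-bin mean predicted risk
#' and observed event fraction. Empty bins are retained with a count of 0 and
#' an absent observed fraction.
#'
#' @param labels Binary outcome per unit.
#' @param predicted_risk Predicted probabilities in \[0,1\].
#' @param n_bins Number of bins (default 20).
#' @return Tibble: `bin`, `risk_lo`, `risk_hi`, `n`, `mean_predicted`,
#'   `observed_fraction`.
#' @export
calibration_table <- function(labels, predicted_risk, n_bins = 20) {
  labels <- check_binary_labels(labels)
  if (length(labels) != length(predicted_risk)) {
    abort_metric("labels/predicted_risk length mismatch")
  }
  if (any(predicted_risk < 0 | predicted_risk > 1, na.rm = TRUE)) {
    abort_validation("predicted_risk must lie in [0,1]")
  }
  bin <- pmin(floor(predicted_risk * n_bins) + 1L, n_bins)
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    risk_lo = (seq_len(n_bins) - 1) / n_bins,
    risk_hi = seq_len(n_bins) / n_bins
  )
  agg <- tibble::tibble(bin = bin, risk = predicted_risk, y = labels) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(), mean_predicted = mean(.data$risk),
                     observed_fraction = mean(.data$y), .groups = "drop")
  out <- dplyr::left_join(out, agg, by = "bin")
  out$n[is.na(out$n)] <- 0L
  out
}
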