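# Evaluation sweeps: the lead-time performance grid and the three clinically
# informed threshold-selection rules (sensitivity-targeted "medium" threshold,
# PPV-targeted "high" threshold, and the max-F1 single threshold). Candidate
# thresholds are always the unique observed scores — no interpolation.

# Confusion stats at every unique observed threshold, descending.
threshold_stats <- function(labels, scores) {
  labels <- check_binary_labels(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) abort_metric("threshold search undefined: no positive labels")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  idx <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[idx]
  tibble::tibble(
    threshold = s[idx],
    tp = tp,
    flagged = idx,
    sensitivity = tp / n_pos,
    ppv = tp / idx,
    f1 = 2 * tp / (idx + n_pos)
  )
}

#' Medium-risk threshold: target a minimum sensitivity
#'
#' Sensitivity is non-increasing in the threshold, so among the unique
#' observed scores this selects the largest threshold whose sensitivity is at
#' least `target` — the tightest achiever. A target of 0 therefore returns
#' the maximum observed score.
#'
#' @inheritParams auroc
#' @param target Sensitivity target in \[0,1\].
#' @param ... Passed to [operating_point()] (e.g. `boot_f1`, `seed`).
#' @return A `dti_operating_point` with extra fields `rule`, `target`,
#'   `attained`.
#' @export
threshold_for_sensitivity <- function(labels, scores, target, ...) {
  if (!is.numeric(target) || target < 0 || target > 1) {
    abort_validation("sensitivity target must lie in [0,1]")
  }
  st <- threshold_stats(labels, scores)
  ok <- which(st$sensitivity >= target)
  # thresholds are descending; the first achiever is the largest threshold
  i <- ok[1]
  op <- operating_point(labels, scores, st$threshold[i], ...)
  op$rule <- "sensitivity_target"
  op$target <- target
  op$attained <- TRUE
  op
}

#' High-risk threshold: target a minimum positive predictive value
#'
#' PPV is not monotone in the threshold, so all unique observed scores are
#' enumerated. Among thresholds achieving `PPV >= target`, the one with
#' maximal sensitivity is returned (ties broken toward higher PPV, then the
#' higher threshold). If no threshold achieves the target, the argmax-PPV
#' threshold is returned with `attained = FALSE`.
#'
#' @inheritParams threshold_for_sensitivity
#' @param target PPV target in \[0,1\].
#' @export
threshold_for_ppv <- function(labels, scores, target, ...) {
  if (!is.numeric(target) || target < 0 || target > 1) {
    abort_validation("PPV target must lie in [0,1]")
  }
  st <- threshold_stats(labels, scores)
  ach <- which(st$ppv >= target)
  if (length(ach)) {
    cand <- st[ach, ]
    cand <- cand[order(-cand$sensitivity, -cand$ppv, -cand$threshold), ]
    thr <- cand$threshold[1]
    attained <- TRUE
  } else {
    cand <- st[order(-st$ppv, -st$sensitivity, -st$threshold), ]
    thr <- cand$threshold[1]
    attained <- FALSE
  }
  op <- operating_point(labels, scores, thr, ...)
  op$rule <- "ppv_target"
  op$target <- target
  op$attained <- attained
  op
}

#' Single threshold: maximize the F1 score
#'
#' Enumerates unique observed scores and returns the F1-maximizing threshold;
#' exact ties in F1 are broken toward the lower threshold (higher
#' sensitivity).
#'
#' @inheritParams threshold_for_sensitivity
#' @export
max_f1_threshold <- function(labels, scores, ...) {
  st <- threshold_stats(labels, scores)
  best <- max(st$f1)
  # descending threshold order: the last argmax is the lowest threshold
  i <- max(which(st$f1 >= best - 1e-12))
  op <- operating_point(labels, scores, st$threshold[i], ...)
  op$rule <- "max_f1"
  op$target <- NA_real_
  op$attained <- TRUE
  op
}

#' Threshold suite: medium, single and high-risk operating points
#'
#' Runs the three selection rules on one labeled set (by default the
#' observation-level labels at the headline 12 h composite setting) and
#' returns them together with the targets used.
#'
#' @inheritParams auroc
#' @param target_sensitivity Sensitivity target for the medium threshold
#'   (default 0.50).
#' @param target_ppv PPV target for the high threshold (default 0.10).
#' @param ... Passed through to [operating_point()].
#' @return A `dti_threshold_suite` list with elements `medium`, `single`,
#'   `high` and `target_parameters`.
#' @export
threshold_suite <- function(labels, scores, target_sensitivity = 0.50,
                            target_ppv = 0.10, ...) {
  structure(
    list(
      medium = threshold_for_sensitivity(labels, scores, target_sensitivity, ...),
      single = max_f1_threshold(labels, scores, ...),
      high = threshold_for_ppv(labels, scores, target_ppv, ...),
      target_parameters = c(target_sensitivity = target_sensitivity,
                            target_ppv = target_ppv)
    ),
    class = "dti_threshold_suite"
  )
}

#' Render a threshold suite as a table
#'
#' One row per performance measure (F1, sensitivity, specificity, PPV, NPV,
#' NNE, threshold), one column per suggested threshold.
#'
#' @param suite A `dti_threshold_suite`.
#' @return Tibble.
#' @export
render_threshold_suite <- function(suite) {
  stopifnot(inherits(suite, "dti_threshold_suite"))
  col <- function(op) {
    c(threshold = op$threshold,
      f1_pct = 100 * op$f1[["est"]],
      sensitivity_pct = 100 * op$sensitivity[["est"]],
      specificity_pct = 100 * op$specificity[["est"]],
      ppv_pct = 100 * op$ppv[["est"]],
      npv_pct = 100 * op$npv[["est"]],
      nne = op$nne[["est"]])
  }
  m <- col(suite$medium); s <- col(suite$single); h <- col(suite$high)
  tibble::tibble(
    measure = names(m),
    medium_risk = unname(m),
    single = unname(s),
    high_risk = unname(h)
  )
}

#' Lead-time performance grid
#'
#' For each outcome scope and lead time, builds observation-level labels with
#' [label_observation_level()] and computes AUROC and average precision. A
#' cell with no positive labels is flagged not estimable and the sweep
#' continues.
#'
#' @param aset A `dti_analysis_set`.
#' @param lead_times_h Lead times in hours (default 3, 6, 12, 24, 38, 72).
#' @param scopes Outcome scopes (default the three components plus the
#'   composite).
#' @param ci Compute bootstrap CIs per cell (cluster bootstrap by encounter).
#' @param B,seed Bootstrap settings when `ci = TRUE`.
#' @return A `dti_lead_time_grid` tibble: `outcome_scope`, `lead_time_h`,
#'   `n`, `n_pos`, `n_neg`, `auroc`, `auprc` (+ CI columns), `estimable`.
#' @export
lead_time_sweep <- function(aset,
                            lead_times_h = c(3, 6, 12, 24, 38, 72),
                            scopes = OUTCOME_SCOPES,
                            ci = FALSE, B = 1000, seed = NULL) {
  stopifnot(inherits(aset, "dti_analysis_set"))
  if (!length(lead_times_h)) abort_validation("lead_times_h must be non-empty")
  rows <- list()
  for (scope in scopes) {
    for (L in lead_times_h) {
      lab <- label_observation_level(aset, L, scope)
      n_pos <- sum(lab$label == 1)
      n_neg <- sum(lab$label == 0)
      row <- tibble::tibble(
        outcome_scope = scope, lead_time_h = L,
        n = nrow(lab), n_pos = n_pos, n_neg = n_neg,
        auroc = NA_real_, auroc_lo = NA_real_, auroc_hi = NA_real_,
        auprc = NA_real_, auprc_lo = NA_real_, auprc_hi = NA_real_,
        estimable = n_pos > 0 && n_neg > 0
      )
      if (row$estimable) {
        cm <- curve_metrics(lab$label, lab$score, ci = ci, B = B, seed = seed,
                            cluster = if (ci) lab$encounter_id else NULL)
        row$auroc <- cm$auroc
        row$auprc <- cm$auprc
        if (ci) {
          row$auroc_lo <- cm$auroc_ci[["lower"]]; row$auroc_hi <- cm$auroc_ci[["upper"]]
          row$auprc_lo <- cm$auprc_ci[["lower"]]; row$auprc_hi <- cm$auprc_ci[["upper"]]
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dti_lead_time_grid", class(out))
  out
}

#' Render a lead-time grid in wide (scope x lead time) layout
#'
#' @param grid A `dti_lead_time_grid`.
#' @param metric `"auroc"` (default) or `"auprc"`.
#' @return Wide tibble, one row per outcome scope, one column per lead time.
#' @export
render_lead_time_grid <- function(grid, metric = c("auroc", "auprc")) {
  metric <- match.arg(metric)
  grid |>
    dplyr::mutate(cell = .data[[metric]]) |>
    dplyr::select("outcome_scope", "lead_time_h", "cell") |>
    tidyr::pivot_wider(names_from = "lead_time_h", values_from = "cell",
                       names_glue = "h{lead_time_h}")
}
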