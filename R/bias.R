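# Subgroup parity audit: AUROC parity, sensitivity parity (equal
# opportunity) and PPV parity (related to false discovery rate parity),
# each the ratio protected-group metric / reference-group metric, plus a
# combined deviation of their sum from the reference value of 3.
# All measurements are at the encounter level.

BIAS_AXES <- c("race", "ethnicity", "sex", "age")

#' Specify a protected / reference subgroup comparison
#'
#' @param axis One of `"race"`, `"ethnicity"`, `"sex"`, `"age"`.
#' @param protected_value Category forming the protected group.
#' @param reference_value Category forming the reference group (White,
#'   other-ethnicity, male and 60-or-older in the default audit).
#' @param age_cut_years Dichotomization cut for the age axis (default 60).
#' @return A `dti_subgroup_spec` list.
#' @export
subgroup_spec <- function(axis, protected_value, reference_value,
                          age_cut_years = 60) {
  axis <- match.arg(axis, BIAS_AXES)
  if (identical(protected_value, reference_value)) {
    abort_validation("protected and reference categories must differ")
  }
  structure(
    list(axis = axis, protected_value = protected_value,
         reference_value = reference_value, age_cut_years = age_cut_years),
    class = "dti_subgroup_spec"
  )
}

# Map each encounter summary row to its category on the given axis.
axis_category <- function(summaries, axis, age_cut_years = 60) {
  if (axis == "age") {
    ifelse(summaries$age_years < age_cut_years, "under_60", "60_and_over")
  } else {
    v <- as.character(summaries[[axis]])
    v[is.na(v) | v == ""] <- "missing"
    v
  }
}

group_metrics <- function(g, threshold) {
  n <- nrow(g)
  n_pos <- sum(g$label == 1)
  n_neg <- n - n_pos
  flagged <- g$max_score >= threshold
  tp <- sum(flagged & g$label == 1)
  list(
    n = n, n_pos = n_pos, n_neg = n_neg,
    auroc = if (n_pos > 0 && n_neg > 0) auroc(g$label, g$max_score) else NA_real_,
    sensitivity = if (n_pos > 0) tp / n_pos else NA_real_,
    ppv = if (sum(flagged) > 0) tp / sum(flagged) else NA_real_,
    n_flagged = sum(flagged)
  )
}

#' Parity report for one protected / reference comparison
#'
#' Computes, at the encounter level, the ratio of the protected group's
#' AUROC, sensitivity and PPV to the reference group's, the sum of the three
#' parities, and the combined deviation `100 * (sum/3 - 1)` (negative =
#' worse than reference). Sensitivity and PPV are measured at the supplied
#' threshold (in the standard audit, the max-F1 threshold computed on the
#' full cohort, not per group).
#'
#' A group failing the estimability preconditions (fewer than `min_n`
#' encounters or `min_events` events, a single outcome class, or no flagged
#' encounters for PPV) yields a flagged, not-estimable row with the group
#' counts — never a silent `NaN`.
#'
#' @param summaries Encounter summaries from [summarize_encounter_level()].
#' @param spec A [subgroup_spec()].
#' @param threshold Score threshold for sensitivity/PPV parity.
#' @param min_n,min_events Minimum group size and event count for an
#'   estimable report (defaults 20 and 2).
#' @return One-row tibble with parities, combined measures, group counts and
#'   an `estimable` flag plus `flag_reason`.
#' @export
parity_report <- function(summaries, spec, threshold, min_n = 20, min_events = 2) {
  stopifnot(inherits(spec, "dti_subgroup_spec"))
  cat_ <- axis_category(summaries, spec$axis, spec$age_cut_years)
  prot <- summaries[cat_ == spec$protected_value, , drop = FALSE]
  ref <- summaries[cat_ == spec$reference_value, , drop = FALSE]

  mp <- group_metrics(prot, threshold)
  mr <- group_metrics(ref, threshold)

  reasons <- character()
  for (side in list(list(m = mp, who = "protected"), list(m = mr, who = "reference"))) {
    m <- side$m
    if (m$n < min_n) reasons <- c(reasons, sprintf("%s group has n < %d", side$who, min_n))
    if (m$n_pos < min_events) {
      reasons <- c(reasons, sprintf("%s group has < %d events", side$who, min_events))
    }
    if (m$n_pos == 0 || m$n_neg == 0) {
      reasons <- c(reasons, sprintf("%s group has a single outcome class", side$who))
    }
    if (m$n_flagged == 0) {
      reasons <- c(reasons, sprintf("%s group has no flagged encounters", side$who))
    }
    if (!is.na(m$sensitivity) && m$sensitivity == 0 && side$who == "reference") {
      reasons <- c(reasons, "reference group has zero sensitivity at threshold")
    }
  }
  estimable <- length(reasons) == 0

  rat <- function(p, r) {
    if (!estimable || is.na(p) || is.na(r) || r == 0) NA_real_ else p / r
  }
  auroc_parity <- rat(mp$auroc, mr$auroc)
  sens_parity <- rat(mp$sensitivity, mr$sensitivity)
  ppv_parity <- rat(mp$ppv, mr$ppv)
  combined_sum <- auroc_parity + sens_parity + ppv_parity

  tibble::tibble(
    axis = spec$axis,
    protected = as.character(spec$protected_value),
    reference = as.character(spec$reference_value),
    n_protected = mp$n, events_protected = mp$n_pos,
    n_reference = mr$n, events_reference = mr$n_pos,
    auroc_parity = auroc_parity,
    sensitivity_parity = sens_parity,
    ppv_parity = ppv_parity,
    combined_sum = combined_sum,
    combined_deviation_pct = if (is.na(combined_sum)) NA_real_ else
      100 * (combined_sum / 3 - 1),
    threshold = threshold,
    estimable = estimable,
    flag_reason = if (estimable) NA_character_ else paste(reasons, collapse = "; ")
  )
}

#' Combined parity deviation
#'
#' `100 * (sum of the three parities / 3 - 1)`: the signed percentage by
#' which the subgroup's summed parity falls short of (negative) or exceeds
#' (positive) the reference value of 3.
#'
#' @param report A one-row parity report from [parity_report()].
#' @return Signed percentage, `NA` when any parity is absent.
#' @export
combined_parity_deviation <- function(report) {
  p <- c(report$auroc_parity, report$sensitivity_parity, report$ppv_parity)
  if (any(is.na(p))) return(NA_real_)
  100 * (sum(p) / 3 - 1)
}

#' Audit every protected subgroup on the requested axes
#'
#' Builds one parity report per protected category per axis: every non-White
#' race category (including chose-not-to-answer and missing) against White;
#' Hispanic and chose-not-to-answer against other-ethnicity; female against
#' male; under-60 against 60-and-over. Small or not-estimable groups are
#' flagged, never silently dropped; an axis whose reference category is
#' absent, or with a single category present, yields a warning and no rows.
#'
#' @param summaries Encounter summaries from [summarize_encounter_level()].
#' @param threshold Score threshold for sensitivity/PPV parity (customarily
#'   the full-cohort max-F1 threshold).
#' @param axes Axes to audit (default all four).
#' @param age_cut_years Age dichotomization cut (default 60).
#' @param min_n,min_events Estimability minima, see [parity_report()].
#' @return Tibble with one row per comparison (a Figure-style parity table).
#' @export
audit_all_subgroups <- function(summaries, threshold,
                                axes = BIAS_AXES,
                                age_cut_years = 60,
                                min_n = 20, min_events = 2) {
  reference_of <- c(race = "White", ethnicity = "other ethnicity",
                    sex = "male", age = "60_and_over")
  rows <- list()
  for (axis in axes) {
    axis <- match.arg(axis, BIAS_AXES)
    cat_ <- axis_category(summaries, axis, age_cut_years)
    ref <- reference_of[[axis]]
    present <- unique(cat_)
    if (!ref %in% present || length(present) < 2) {
      rlang::warn(sprintf(
        "axis '%s': reference category '%s' absent or single category present; skipped",
        axis, ref
      ))
      next
    }
    for (lev in sort(setdiff(present, ref))) {
      sp <- subgroup_spec(axis, lev, ref, age_cut_years)
      rows[[length(rows) + 1]] <-
        parity_report(summaries, sp, threshold, min_n = min_n, min_events = min_events)
    }
  }
  dplyr::bind_rows(rows)
}
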