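# Labeling: turn the analysis set into labeled units at the two evaluation
# levels. Observation level: every retained score is a unit and its label asks
# whether a qualifying event falls in the half-open window (ts, ts + L].
# Encounter level: one unit per hospitalization, the maximum retained score.

OUTCOME_SCOPES <- c("mechanical_ventilation", "icu_transfer", "death", "composite")

#' Label every retained prediction against a lead-time window
#'
#' A prediction at time `t` is labeled positive when the qualifying event lies
#' in the half-open window `(t, t + lead_time_h]`: open at the prediction
#' instant (a score concurrent with the event was already excluded upstream)
#' and closed at the horizon. For `outcome_scope = "composite"` the
#' qualifying event is the encounter's first deterioration event of any type;
#' for a component scope it is the first event of that type, even if another
#' component occurred earlier (predictions after the composite first event do
#' not exist by construction).
#'
#' @param aset A `dti_analysis_set`.
#' @param lead_time_h Positive lead time (horizon) in hours.
#' @param outcome_scope One of `"composite"` (default),
#'   `"mechanical_ventilation"`, `"icu_transfer"`, `"death"`.
#' @return Tibble with one row per retained prediction: `encounter_id`, `ts`,
#'   `rel_min`, `score`, `lead_time_h`, `outcome_scope`, `label` (0/1).
#' @export
label_observation_level <- function(aset, lead_time_h, outcome_scope = "composite") {
  stopifnot(inherits(aset, "dti_analysis_set"))
  if (!is.numeric(lead_time_h) || length(lead_time_h) != 1 || lead_time_h <= 0) {
    abort_validation("lead_time_h must be a single positive number")
  }
  outcome_scope <- match.arg(outcome_scope, OUTCOME_SCOPES)

  ev <- if (outcome_scope == "composite") {
    aset$first_events
  } else {
    first_events_by_encounter(
      aset$events[aset$events$event_type == outcome_scope, , drop = FALSE],
      aset$params$event_type_priority
    )
  }

  prd <- dplyr::left_join(
    aset$predictions,
    stats::setNames(ev[, c("encounter_id", "rel_min")], c("encounter_id", ".ev_rel")),
    by = "encounter_id"
  )
  window_min <- lead_time_h * 60
  lab <- !is.na(prd$.ev_rel) &
    prd$.ev_rel > prd$rel_min &
    prd$.ev_rel <= prd$rel_min + window_min

  tibble::tibble(
    encounter_id = prd$encounter_id,
    ts = prd$ts,
    rel_min = prd$rel_min,
    score = prd$score,
    lead_time_h = lead_time_h,
    outcome_scope = outcome_scope,
    label = as.integer(lab)
  )
}

#' Encounter-level summaries: maximum pre-event score and outcome label
#'
#' One unit per hospitalization. The score is the maximum over retained
#' (pre-event, post-exclusion) predictions; ties in the maximum resolve to
#' the earliest occurrence for `max_score_ts`. The label is 1 when the
#' encounter has a first deterioration event (the outcome occurred any time
#' after scoring began). Demographic attributes are carried from the
#' encounter for downstream subgroup analysis.
#'
#' @param aset A `dti_analysis_set`.
#' @return Tibble with columns `encounter_id`, `max_score`, `max_score_ts`,
#'   `label`, `age_years`, `sex`, `race`, `ethnicity`.
#' @export
summarize_encounter_level <- function(aset) {
  stopifnot(inherits(aset, "dti_analysis_set"))
  prd <- aset$predictions
  if (!all(aset$encounters$encounter_id %in% prd$encounter_id)) {
    rlang::abort("encounter with no retained predictions reached encounter-level summary",
                 class = "detvalid_internal_error")
  }
  summ <- prd |>
    dplyr::group_by(.data$encounter_id) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$rel_min, .by_group = TRUE) |>
    dplyr::summarise(max_score = .data$score[1], max_score_ts = .data$ts[1],
                     .groups = "drop")
  summ$label <- as.integer(summ$encounter_id %in% aset$first_events$encounter_id)
  demo <- aset$encounters[, intersect(
    c("encounter_id", "age_years", "sex", "race", "ethnicity"),
    names(aset$encounters)
  )]
  dplyr::left_join(summ, demo, by = "encounter_id")
}
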