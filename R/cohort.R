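# Cohort ingest: parsing, validation and the exclusion cascade that turns raw
# encounter / prediction / event tables into the analysis set.

LOCATION_CLASSES <- c("ward", "icu", "preop", "intraop", "labor_delivery", "other")
EVENT_TYPES <- c("mechanical_ventilation", "icu_transfer", "death")
DEFAULT_EXCLUDED_LOCATIONS <- c("preop", "intraop", "icu", "labor_delivery")
DEFAULT_EVENT_PRIORITY <- c("mechanical_ventilation", "icu_transfer", "death")

read_table_input <- function(x, what) {
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort_schema(sprintf("%s table not found at '%s'", what, x))
    ext <- tolower(tools::file_ext(x))
    if (ext %in% c("parquet", "pq")) {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        abort_schema("reading Parquet requires the 'arrow' package")
      }
      return(tibble::as_tibble(arrow::read_parquet(x)))
    }
    return(readr::read_csv(x, show_col_types = FALSE, progress = FALSE))
  }
  abort_schema(sprintf("%s input must be a data frame or a file path", what))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_schema(sprintf(
      "%s table is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
}

#' Parse and validate the three cohort input tables
#'
#' Reads the encounters, predictions and events tables (data frames, CSV paths
#' or Parquet paths), coerces timestamps to POSIXct (UTC), checks every
#' record-level invariant, and attaches the relative time of each prediction
#' and event in minutes since its encounter's admission (all window arithmetic
#' downstream is done in minutes).
#'
#' Required columns:
#' * `encounters`: `encounter_id`, `admission_ts`, `discharge_ts`,
#'   `age_years`, `sex`, `race`, `ethnicity`; optional `patient_id`,
#'   `hospital_id`, `code_status`, `comfort_care_ts` and any number of
#'   `comorbidity_*` flag columns.
#' * `predictions`: `encounter_id`, `ts`, `score` (in \[0,100\]),
#'   `location_class` (one of ward, icu, preop, intraop, labor_delivery,
#'   other).
#' * `events`: `encounter_id`, `event_type` (mechanical_ventilation,
#'   icu_transfer, death), `ts`. Death events must be timestamped at the
#'   encounter's discharge (death is defined as time of discharge).
#'
#' Violations raise classed conditions: `detvalid_schema_error` for missing
#' columns, `detvalid_validation_error` (naming offending row indices) for
#' out-of-range scores or timestamps outside the encounter span.
#'
#' @param encounters,predictions,events Data frames or file paths.
#' @return A `dti_cohort`: list with tibbles `encounters`, `predictions`,
#'   `events` (each with `rel_min` columns on time-stamped rows) and `n_raw`
#'   input row counts.
#' @seealso [build_analysis_set()]
#' @export
parse_cohort <- function(encounters, predictions, events) {
  enc <- read_table_input(encounters, "encounters")
  prd <- read_table_input(predictions, "predictions")
  evt <- read_table_input(events, "events")

  require_columns(enc, c("encounter_id", "admission_ts", "discharge_ts",
                         "age_years", "sex", "race", "ethnicity"), "encounters")
  require_columns(prd, c("encounter_id", "ts", "score", "location_class"), "predictions")
  require_columns(evt, c("encounter_id", "event_type", "ts"), "events")

  enc$encounter_id <- as.character(enc$encounter_id)
  prd$encounter_id <- as.character(prd$encounter_id)
  evt$encounter_id <- as.character(evt$encounter_id)

  enc$admission_ts <- parse_ts(enc$admission_ts, "admission_ts")
  enc$discharge_ts <- parse_ts(enc$discharge_ts, "discharge_ts")
  if (!"comfort_care_ts" %in% names(enc)) enc$comfort_care_ts <- enc$admission_ts[NA]
  enc$comfort_care_ts <- parse_ts(enc$comfort_care_ts, "comfort_care_ts")
  if (!"code_status" %in% names(enc)) enc$code_status <- "missing"
  if (!"patient_id" %in% names(enc)) enc$patient_id <- enc$encounter_id
  if (!"hospital_id" %in% names(enc)) enc$hospital_id <- "H1"
  prd$ts <- parse_ts(prd$ts, "prediction ts")
  evt$ts <- parse_ts(evt$ts, "event ts")

  if (anyDuplicated(enc$encounter_id)) {
    abort_validation("duplicate encounter_id in encounters table")
  }

  bad <- which(!(enc$admission_ts < enc$discharge_ts))
  if (length(bad)) {
    abort_validation(sprintf(
      "admission_ts must precede discharge_ts; violated at encounter row(s) %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  bad <- which(is.na(enc$age_years) | enc$age_years < 0)
  if (length(bad)) {
    abort_validation(sprintf("age_years missing or negative at encounter row(s) %s",
                             paste(utils::head(bad, 5), collapse = ", ")))
  }
  cc <- !is.na(enc$comfort_care_ts)
  bad <- which(cc & (enc$comfort_care_ts < enc$admission_ts |
                       enc$comfort_care_ts > enc$discharge_ts))
  if (length(bad)) {
    abort_validation(sprintf(
      "comfort_care_ts outside encounter span at encounter row(s) %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }

  bad <- which(is.na(prd$score) | prd$score < 0 | prd$score > 100)
  if (length(bad)) {
    abort_validation(sprintf(
      "score outside [0,100] at prediction row(s) %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  bad <- which(!prd$location_class %in% LOCATION_CLASSES)
  if (length(bad)) {
    abort_validation(sprintf(
      "unknown location_class at prediction row(s) %s (allowed: %s)",
      paste(utils::head(bad, 5), collapse = ", "),
      paste(LOCATION_CLASSES, collapse = ", ")
    ))
  }
  bad <- which(!evt$event_type %in% EVENT_TYPES)
  if (length(bad)) {
    abort_validation(sprintf(
      "unknown event_type at event row(s) %s (allowed: %s)",
      paste(utils::head(bad, 5), collapse = ", "),
      paste(EVENT_TYPES, collapse = ", ")
    ))
  }

  span <- enc[, c("encounter_id", "admission_ts", "discharge_ts")]
  prd <- dplyr::left_join(prd, span, by = "encounter_id")
  bad <- which(is.na(prd$admission_ts))
  if (length(bad)) {
    abort_validation(sprintf(
      "prediction row(s) %s reference unknown encounter_id",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  bad <- which(prd$ts < prd$admission_ts | prd$ts > prd$discharge_ts)
  if (length(bad)) {
    abort_validation(sprintf(
      "prediction timestamp outside encounter span at row(s) %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  prd$rel_min <- minutes_between(prd$admission_ts, prd$ts)
  prd$admission_ts <- NULL
  prd$discharge_ts <- NULL

  evt <- dplyr::left_join(evt, span, by = "encounter_id")
  bad <- which(is.na(evt$admission_ts))
  if (length(bad)) {
    abort_validation(sprintf(
      "event row(s) %s reference unknown encounter_id",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  bad <- which(evt$ts < evt$admission_ts | evt$ts > evt$discharge_ts)
  if (length(bad)) {
    abort_validation(sprintf(
      "event timestamp outside encounter span at row(s) %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  # Death is defined as time of discharge; allow sub-minute slack for I/O round-trips.
  dth <- which(evt$event_type == "death" &
                 abs(minutes_between(evt$ts, evt$discharge_ts)) > 1)
  if (length(dth)) {
    abort_validation(sprintf(
      "death event not timestamped at discharge at event row(s) %s",
      paste(utils::head(dth, 5), collapse = ", ")
    ))
  }
  evt$rel_min <- minutes_between(evt$admission_ts, evt$ts)
  evt$admission_ts <- NULL
  evt$discharge_ts <- NULL

  structure(
    list(
      encounters = enc,
      predictions = prd,
      events = evt,
      n_raw = c(encounters = nrow(enc), predictions = nrow(prd), events = nrow(evt))
    ),
    class = "dti_cohort"
  )
}

#' Drop predictions made in excluded care locations
#'
#' Scores produced in locations where the outcome is not meaningfully
#' predictable (planned intubation in operating areas, patients already in
#' intensive care, labor and delivery) are removed before analysis.
#'
#' @param predictions Tibble of prediction records.
#' @param excluded_locations Character vector of location classes to drop;
#'   defaults to preoperative, intraoperative, ICU and labor-and-delivery.
#' @return The filtered tibble, with attribute `n_removed`. Warns if nothing
#'   survives.
#' @export
exclude_by_location <- function(predictions,
                                excluded_locations = DEFAULT_EXCLUDED_LOCATIONS) {
  keep <- !predictions$location_class %in% excluded_locations
  out <- predictions[keep, , drop = FALSE]
  if (nrow(out) == 0 && nrow(predictions) > 0) {
    rlang::warn("all predictions fall in excluded locations; result is empty")
  }
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' First deterioration event of one encounter
#'
#' Returns the earliest event; ties at an identical timestamp are resolved by
#' a fixed type priority (mechanical ventilation, then ICU transfer, then
#' death) — ventilation is the most specific escalation and death timestamps
#' (discharge time) are coarse.
#'
#' @param events Tibble of events for a single encounter.
#' @param priority Event-type priority for timestamp ties.
#' @return One-row tibble, or `NULL` when there are no events.
#' @export
first_deterioration <- function(events, priority = DEFAULT_EVENT_PRIORITY) {
  if (is.null(events) || nrow(events) == 0) return(NULL)
  if (length(unique(events$encounter_id)) > 1) {
    abort_validation("first_deterioration() expects events from a single encounter")
  }
  ord <- order(events$ts, match(events$event_type, priority))
  events[ord[1], , drop = FALSE]
}

# Vectorised first event per encounter (same tie rule as first_deterioration).
first_events_by_encounter <- function(events, priority = DEFAULT_EVENT_PRIORITY) {
  if (nrow(events) == 0) {
    return(events[0, c("encounter_id", "event_type", "ts", "rel_min")])
  }
  events |>
    dplyr::mutate(.prio = match(.data$event_type, priority)) |>
    dplyr::arrange(.data$encounter_id, .data$ts, .data$.prio) |>
    dplyr::distinct(.data$encounter_id, .keep_all = TRUE) |>
    dplyr::select("encounter_id", "event_type", "ts", "rel_min")
}

ledger_row <- function(step, unit, n_removed, n_remaining) {
  tibble::tibble(step = step, unit = unit,
                 n_removed = as.integer(n_removed),
                 n_remaining = as.integer(n_remaining))
}

#' Build the analysis set by applying the study exclusion cascade
#'
#' Applies, in order: (0) removal of encounters under the minimum age;
#' (1) care-location exclusion of predictions; (2) computation of each
#' encounter's first deterioration event; (3) removal of whole encounters in
#' which a comfort-care order precedes the first deterioration event;
#' (4) removal of predictions at or after the first event (a score concurrent
#' with deterioration offers no warning, so the boundary is closed);
#' (5) removal of encounters left with no predictions. Every removal is
#' recorded in an exclusion ledger; nothing is dropped silently.
#'
#' @param cohort A `dti_cohort` from [parse_cohort()].
#' @param excluded_locations Location classes removed at step 1.
#' @param event_type_priority Tie rule for simultaneous events.
#' @param minimum_age Minimum age in years for inclusion (default 18).
#' @return A `dti_analysis_set`: list with tibbles `encounters`,
#'   `predictions`, `events` (all retained events, for component-outcome
#'   labeling), `first_events`, the `exclusion_ledger`, and the parameters
#'   used.
#' @export
build_analysis_set <- function(cohort,
                               excluded_locations = DEFAULT_EXCLUDED_LOCATIONS,
                               event_type_priority = DEFAULT_EVENT_PRIORITY,
                               minimum_age = 18) {
  stopifnot(inherits(cohort, "dti_cohort"))
  enc <- cohort$encounters
  prd <- cohort$predictions
  evt <- cohort$events
  ledger <- list()

  # Step 0: age inclusion.
  underage <- enc$encounter_id[enc$age_years < minimum_age]
  n_prd0 <- sum(prd$encounter_id %in% underage)
  enc <- enc[!enc$encounter_id %in% underage, , drop = FALSE]
  prd <- prd[!prd$encounter_id %in% underage, , drop = FALSE]
  evt <- evt[!evt$encounter_id %in% underage, , drop = FALSE]
  ledger[[length(ledger) + 1]] <-
    ledger_row("age_below_minimum", "encounter", length(underage), nrow(enc))
  ledger[[length(ledger) + 1]] <-
    ledger_row("age_below_minimum", "prediction", n_prd0, nrow(prd))

  # Step 1: location exclusion.
  prd1 <- exclude_by_location(prd, excluded_locations)
  ledger[[length(ledger) + 1]] <-
    ledger_row("location_exclusion", "prediction", attr(prd1, "n_removed"), nrow(prd1))
  prd <- prd1

  # Step 2: first deterioration event per encounter.
  fe <- first_events_by_encounter(evt, event_type_priority)

  # Step 3: comfort-care order preceding first deterioration -> drop encounter.
  cc <- enc[!is.na(enc$comfort_care_ts),
            c("encounter_id", "comfort_care_ts"), drop = FALSE]
  cc <- dplyr::inner_join(cc, fe[, c("encounter_id", "ts")], by = "encounter_id")
  drop_cc <- cc$encounter_id[cc$comfort_care_ts < cc$ts]
  n_prd3 <- sum(prd$encounter_id %in% drop_cc)
  enc <- enc[!enc$encounter_id %in% drop_cc, , drop = FALSE]
  prd <- prd[!prd$encounter_id %in% drop_cc, , drop = FALSE]
  evt <- evt[!evt$encounter_id %in% drop_cc, , drop = FALSE]
  fe <- fe[!fe$encounter_id %in% drop_cc, , drop = FALSE]
  ledger[[length(ledger) + 1]] <-
    ledger_row("comfort_care_before_event", "encounter", length(drop_cc), nrow(enc))
  ledger[[length(ledger) + 1]] <-
    ledger_row("comfort_care_before_event", "prediction", n_prd3, nrow(prd))

  # Step 4: predictions at or after the first event (closed boundary).
  prd <- dplyr::left_join(
    prd,
    stats::setNames(fe[, c("encounter_id", "rel_min")], c("encounter_id", ".ev_rel")),
    by = "encounter_id"
  )
  post <- !is.na(prd$.ev_rel) & prd$rel_min >= prd$.ev_rel
  n_prd4 <- sum(post)
  prd <- prd[!post, , drop = FALSE]
  prd$.ev_rel <- NULL
  ledger[[length(ledger) + 1]] <-
    ledger_row("post_event_prediction", "prediction", n_prd4, nrow(prd))

  # Step 5: encounters with no remaining predictions.
  empty <- setdiff(enc$encounter_id, unique(prd$encounter_id))
  enc <- enc[!enc$encounter_id %in% empty, , drop = FALSE]
  evt <- evt[!evt$encounter_id %in% empty, , drop = FALSE]
  fe <- fe[!fe$encounter_id %in% empty, , drop = FALSE]
  ledger[[length(ledger) + 1]] <-
    ledger_row("no_remaining_predictions", "encounter", length(empty), nrow(enc))

  out <- structure(
    list(
      encounters = enc,
      predictions = prd,
      events = evt,
      first_events = fe,
      exclusion_ledger = dplyr::bind_rows(ledger),
      params = list(excluded_locations = excluded_locations,
                    event_type_priority = event_type_priority,
                    minimum_age = minimum_age),
      n_input = cohort$n_raw
    ),
    class = "dti_analysis_set"
  )
  assert_analysis_set(out)
  out
}

# Loud invariant checks; these can only fire on an implementation defect.
assert_analysis_set <- function(aset) {
  prd <- dplyr::left_join(
    aset$predictions,
    stats::setNames(aset$first_events[, c("encounter_id", "rel_min")],
                    c("encounter_id", ".ev_rel")),
    by = "encounter_id"
  )
  if (any(!is.na(prd$.ev_rel) & prd$rel_min >= prd$.ev_rel)) {
    rlang::abort("internal invariant violated: prediction at or after first event",
                 class = "detvalid_internal_error")
  }
  if (!all(aset$encounters$encounter_id %in% aset$predictions$encounter_id)) {
    rlang::abort("internal invariant violated: encounter with no predictions retained",
                 class = "detvalid_internal_error")
  }
  invisible(aset)
}

#' @export
print.dti_analysis_set <- function(x, ...) {
  cat("<dti_analysis_set>\n")
  cat(sprintf("  encounters : %d (of %d input)\n",
              nrow(x$encounters), x$n_input[["encounters"]]))
  cat(sprintf("  predictions: %d (of %d input)\n",
              nrow(x$predictions), x$n_input[["predictions"]]))
  cat(sprintf("  deteriorations: %d encounters\n", nrow(x$first_events)))
  cat("  exclusion ledger:\n")
  lg <- x$exclusion_ledger
  for (i in seq_len(nrow(lg))) {
    cat(sprintf("    %-28s %-10s removed %6d, remaining %6d\n",
                lg$step[i], lg$unit[i], lg$n_removed[i], lg$n_remaining[i]))
  }
  invisible(x)
}

med_iqr <- function(x) {
  if (!length(x)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Descriptive cohort summary stratified by deterioration
#'
#' Counts and percentages of demographics (and any `comorbidity_*` flag
#' columns) by deterioration stratum, plus median (IQR) length of stay in
#' days and median (IQR) time from admission to the first deterioration
#' event in hours. Percentages for an empty stratum are reported as `NA`,
#' never as zero.
#'
#' @param aset A `dti_analysis_set`.
#' @return A `dti_cohort_summary` list: `n_encounters`, `n_deterioration`,
#'   `prevalence_pct`, long tibble `characteristics`, and tibble `durations`.
#' @export
describe_cohort <- function(aset) {
  stopifnot(inherits(aset, "dti_analysis_set"))
  enc <- aset$encounters
  if (nrow(enc) == 0) abort_validation("empty analysis set")
  det_ids <- aset$first_events$encounter_id
  enc$deteriorated <- enc$encounter_id %in% det_ids

  strata <- list(
    overall = enc,
    no_deterioration = enc[!enc$deteriorated, , drop = FALSE],
    deterioration = enc[enc$deteriorated, , drop = FALSE]
  )

  cat_cols <- c("sex", "race", "ethnicity", "code_status")
  cat_cols <- intersect(cat_cols, names(enc))
  comorb <- grep("^comorbidity_", names(enc), value = TRUE)

  rows <- list()
  for (sname in names(strata)) {
    s <- strata[[sname]]
    n <- nrow(s)
    for (col in cat_cols) {
      tab <- table(s[[col]], useNA = "no")
      for (lev in names(tab)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          characteristic = col, level = lev, stratum = sname,
          n = as.integer(tab[[lev]]),
          pct = if (n > 0) pct(tab[[lev]], n) else NA_real_
        )
      }
    }
    for (col in comorb) {
      k <- sum(s[[col]] %in% c(TRUE, 1))
      rows[[length(rows) + 1]] <- tibble::tibble(
        characteristic = "comorbidity", level = sub("^comorbidity_", "", col),
        stratum = sname, n = as.integer(k),
        pct = if (n > 0) pct(k, n) else NA_real_
      )
    }
  }

  los_days <- lapply(strata, function(s) {
    med_iqr(minutes_between(s$admission_ts, s$discharge_ts) / 1440)
  })
  tte_h <- med_iqr(aset$first_events$rel_min / 60)

  durations <- dplyr::bind_rows(
    tibble::tibble(quantity = "length_of_stay_days",
                   stratum = names(los_days),
                   median = unname(vapply(los_days, `[[`, 0, "median")),
                   q1 = unname(vapply(los_days, `[[`, 0, "q1")),
                   q3 = unname(vapply(los_days, `[[`, 0, "q3"))),
    tibble::tibble(quantity = "time_to_first_event_hours",
                   stratum = "deterioration",
                   median = tte_h[["median"]], q1 = tte_h[["q1"]], q3 = tte_h[["q3"]])
  )

  structure(
    list(
      n_encounters = nrow(enc),
      n_deterioration = length(det_ids),
      prevalence_pct = pct(length(det_ids), nrow(enc)),
      characteristics = dplyr::bind_rows(rows),
      durations = durations
    ),
    class = "dti_cohort_summary"
  )
}

#' @export
print.dti_cohort_summary <- function(x, ...) {
  cat("<dti_cohort_summary>\n")
  cat(sprintf("  encounters: %d; deterioration: %d (%.1f%%)\n",
              x$n_encounters, x$n_deterioration, x$prevalence_pct))
  print(x$durations)
  invisible(x)
}
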