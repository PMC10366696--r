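# Cohort ingest: parsing, validation errors, the exclusion cascade and its
# ledger accounting.

test_that("parsing typed records from toy tables preserves counts and types", {
  tt <- make_toy_tables()
  co <- parse_cohort(tt$encounters, tt$predictions, tt$events)
  expect_s3_class(co, "dti_cohort")
  expect_identical(unname(co$n_raw),
                   c(nrow(tt$encounters), nrow(tt$predictions), nrow(tt$events)))
  expect_true(all(c("rel_min") %in% names(co$predictions)))
  # relative minutes measured from admission
  expect_equal(co$predictions$rel_min[1], 60)
})

test_that("schema and validation errors name the offending column or row", {
  tt <- make_toy_tables()
  expect_error(
    parse_cohort(dplyr::select(tt$encounters, -sex), tt$predictions, tt$events),
    "sex", class = "detvalid_schema_error"
  )
  bad_pred <- tt$predictions
  bad_pred$score[4] <- 105
  expect_error(parse_cohort(tt$encounters, bad_pred, tt$events),
               "row\\(s\\) 4", class = "detvalid_validation_error")
  bad_ev <- tt$events
  bad_ev$ts[1] <- ts_at(-5) # before admission
  expect_error(parse_cohort(tt$encounters, tt$predictions, bad_ev),
               "outside encounter span", class = "detvalid_validation_error")
  bad_ev2 <- tt$events
  bad_ev2$ts[2] <- ts_at(20) # death not at discharge
  expect_error(parse_cohort(tt$encounters, tt$predictions, bad_ev2),
               "death", class = "detvalid_validation_error")
})

test_that("location exclusion filters the configured classes", {
  prd <- tibble::tibble(
    encounter_id = "X", ts = ts_at(1:5), rel_min = (1:5) * 60,
    score = 50,
    location_class = c("ward", "icu", "ward", "icu", "other")
  )
  out <- exclude_by_location(prd)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_removed"), 2)
  # empty exclusion set is the identity
  expect_equal(nrow(exclude_by_location(prd, character(0))), 5)
  # everything excluded -> empty result plus a warning
  expect_warning(out0 <- exclude_by_location(prd, unique(prd$location_class)),
                 "excluded locations")
  expect_equal(nrow(out0), 0)
})

test_that("first deterioration is the earliest event with the type-priority tie rule", {
  ev <- tibble::tibble(
    encounter_id = "X",
    event_type = c("mechanical_ventilation", "icu_transfer"),
    ts = ts_at(c(20, 25)), rel_min = c(20, 25) * 60
  )
  expect_equal(first_deterioration(ev)$event_type, "mechanical_ventilation")
  expect_null(first_deterioration(ev[0, ]))
  tie <- ev
  tie$ts <- ts_at(c(20, 20)); tie$rel_min <- c(20, 20) * 60
  tie$event_type <- c("icu_transfer", "mechanical_ventilation")
  expect_equal(first_deterioration(tie)$event_type, "mechanical_ventilation")
})

test_that("the exclusion cascade removes exactly what the rules say", {
  aset <- make_toy_analysis_set()
  # C removed whole (comfort care precedes death); E and F emptied; A, B, D stay
  expect_setequal(aset$encounters$encounter_id, c("A", "B", "D"))
  lg <- aset$exclusion_ledger
  expect_equal(lg$n_removed[lg$step == "comfort_care_before_event" &
                              lg$unit == "encounter"], 1)
  expect_equal(lg$n_removed[lg$step == "no_remaining_predictions"], 2)
  # B's prediction at 31 h (post ICU transfer at 30 h) is gone, 2 remain
  expect_equal(sum(aset$predictions$encounter_id == "B"), 2)
  # prediction exactly at the event time counts as post-event (closed boundary)
  tt <- make_toy_tables()
  tt$predictions$ts[5] <- ts_at(30) # B's second prediction moved onto the event
  aset2 <- build_analysis_set(parse_cohort(tt$encounters, tt$predictions, tt$events))
  expect_equal(sum(aset2$predictions$encounter_id == "B"), 1)
})

test_that("prediction counts are conserved across the ledger", {
  aset <- make_toy_analysis_set()
  lg <- aset$exclusion_ledger
  removed <- sum(lg$n_removed[lg$unit == "prediction"])
  expect_equal(aset$n_input[["predictions"]], nrow(aset$predictions) + removed)
})

test_that("rebuilding from the analysis set's own tables changes nothing", {
  aset <- make_toy_analysis_set()
  again <- build_analysis_set(
    parse_cohort(aset$encounters, aset$predictions, aset$events)
  )
  expect_equal(again$encounters$encounter_id, aset$encounters$encounter_id)
  expect_equal(again$predictions$score, aset$predictions$score)
  expect_equal(sum(again$exclusion_ledger$n_removed), 0)
})

test_that("input row order does not affect the analysis set", {
  tt <- make_toy_tables()
  set.seed(4)
  tt2 <- lapply(tt, function(df) df[sample(nrow(df)), , drop = FALSE])
  a1 <- build_analysis_set(parse_cohort(tt$encounters, tt$predictions, tt$events))
  a2 <- build_analysis_set(parse_cohort(tt2$encounters, tt2$predictions, tt2$events))
  key <- function(a) {
    p <- a$predictions[order(a$predictions$encounter_id, a$predictions$rel_min), ]
    list(sort(a$encounters$encounter_id), p$score, p$rel_min)
  }
  expect_equal(key(a1), key(a2))
})

test_that("under-age encounters are excluded with ledger accounting", {
  tt <- make_toy_tables()
  tt$encounters$age_years[4] <- 17 # encounter D
  aset <- build_analysis_set(parse_cohort(tt$encounters, tt$predictions, tt$events))
  expect_false("D" %in% aset$encounters$encounter_id)
  lg <- aset$exclusion_ledger
  expect_equal(lg$n_removed[lg$step == "age_below_minimum" & lg$unit == "encounter"], 1)
})

test_that("cohort description reports prevalence, strata and durations", {
  aset <- make_toy_analysis_set()
  d <- describe_cohort(aset)
  expect_equal(d$n_encounters, 3)
  expect_equal(d$n_deterioration, 1)
  expect_equal(d$prevalence_pct, pct(1, 3))
  expect_true("time_to_first_event_hours" %in% d$durations$quantity)
  # single encounter, no event: prevalence 0, LOS equals that encounter's stay
  tt <- make_toy_tables()
  one <- build_analysis_set(parse_cohort(tt$encounters[1, ],
                                         tt$predictions[1:3, ],
                                         tt$events[0, ]))
  d1 <- describe_cohort(one)
  expect_equal(d1$prevalence_pct, 0)
  los <- d1$durations[d1$durations$quantity == "length_of_stay_days" &
                        d1$durations$stratum == "overall", ]
  expect_equal(los$median, 2) # 48 h
  # empty stratum percentages are absent, not zero
  tte <- d1$durations[d1$durations$quantity == "time_to_first_event_hours", ]
  expect_true(is.na(tte$median))
})

test_that("CSV round-trip through files parses identically", {
  tt <- make_toy_tables()
  dir <- withr::local_tempdir()
  readr::write_csv(tt$encounters, file.path(dir, "enc.csv"))
  readr::write_csv(tt$predictions, file.path(dir, "prd.csv"))
  readr::write_csv(tt$events, file.path(dir, "evt.csv"))
  co <- parse_cohort(file.path(dir, "enc.csv"), file.path(dir, "prd.csv"),
                     file.path(dir, "evt.csv"))
  expect_equal(nrow(co$predictions), nrow(tt$predictions))
  expect_equal(co$predictions$rel_min,
               parse_cohort(tt$encounters, tt$predictions, tt$events)$predictions$rel_min)
})
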