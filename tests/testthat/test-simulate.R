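# Synthetic cohort generator: determinism, stream integrity, prevalence
# control, the closed-form binormal identity, and bias injection.

test_that("identical seeds give identical tables; substreams isolate encounters", {
  cfg <- sim_config(n_encounters = 25, seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$predictions, s2$predictions)
  expect_identical(s1$encounters, s2$encounters)
  expect_identical(s1$events, s2$events)
  # growing the cohort leaves existing encounters untouched
  s3 <- simulate_cohort(sim_config(n_encounters = 40, seed = 99))
  first25 <- s3$predictions[s3$predictions$encounter_id %in%
                              s1$predictions$encounter_id, ]
  expect_identical(first25$score, s1$predictions$score)
})

test_that("score streams tick every interval and stay inside the stay", {
  sim <- simulate_cohort(sim_config(n_encounters = 50, seed = 5))
  joined <- dplyr::left_join(
    sim$predictions,
    sim$encounters[, c("encounter_id", "admission_ts", "discharge_ts")],
    by = "encounter_id"
  )
  expect_true(all(joined$ts >= joined$admission_ts))
  expect_true(all(joined$ts <= joined$discharge_ts))
  gaps <- joined |>
    dplyr::group_by(encounter_id) |>
    dplyr::summarise(ok = all(diff(as.numeric(ts)) == 15 * 60), .groups = "drop")
  expect_true(all(gaps$ok))
  expect_true(all(joined$score >= 0 & joined$score <= 100))
})

test_that("generator output satisfies every parse-time invariant", {
  sim <- simulate_cohort(sim_config(n_encounters = 60, seed = 8))
  expect_no_error(parse_cohort(sim$encounters, sim$predictions, sim$events))
  # death events sit exactly at discharge
  dth <- sim$events[sim$events$event_type == "death", ]
  if (nrow(dth)) {
    dis <- sim$encounters$discharge_ts[match(dth$encounter_id,
                                             sim$encounters$encounter_id)]
    expect_equal(as.numeric(dth$ts), as.numeric(dis))
  }
  # ICU transfer flips subsequent locations to icu
  icu_enc <- sim$events$encounter_id[sim$events$event_type == "icu_transfer"]
  if (length(icu_enc)) {
    e <- icu_enc[1]
    ev_ts <- sim$events$ts[sim$events$encounter_id == e][1]
    after <- sim$predictions[sim$predictions$encounter_id == e &
                               sim$predictions$ts >= ev_ts, ]
    expect_true(all(after$location_class == "icu"))
  }
})

test_that("realized prevalence tracks the target within one point at n = 1e4", {
  sim <- simulate_cohort(sim_config(n_encounters = 1e4, seed = 12))
  realized <- length(unique(sim$events$encounter_id)) / 1e4
  expect_lt(abs(realized - 0.103), 0.01)
})

test_that("zero event rate produces no events anywhere", {
  s0 <- simulate_cohort(sim_config(n_encounters = 30, seed = 3,
                                   event_prevalence = 0))
  expect_equal(nrow(s0$events), 0)
  h0 <- simulate_cohort(sim_config(n_encounters = 30, seed = 3, mode = "hazard",
                                   hazard_params = list(baseline_hazard = 0)))
  expect_equal(nrow(h0$events), 0)
})

test_that("theoretical binormal AUROC has the closed normal-CDF form", {
  expect_equal(theoretical_auroc(50, 50, 10, 10), 0.5)
  expect_equal(theoretical_auroc(35, 35 + 12 * sqrt(2), 12, 12),
               pnorm(1), tolerance = 1e-12)
  expect_equal(round(theoretical_auroc(35, 35 + 12 * sqrt(2), 12, 12), 4), 0.8413)
  expect_gt(theoretical_auroc(20, 80, 5, 5), 0.9999)
  expect_warning(theoretical_auroc(5, 50, 10, 10), "truncated")
  expect_error(theoretical_auroc(40, 60, 0, 10), class = "detvalid_config_error")
})

test_that("hazard-mode baseline calibration hits the prevalence target", {
  cfg <- sim_config(n_encounters = 3000, seed = 17, mode = "hazard")
  sim <- simulate_cohort(cfg)
  realized <- length(unique(sim$events$encounter_id)) / 3000
  expect_lt(abs(realized - 0.103), 0.03)
  expect_error(
    simulate_cohort(sim_config(n_encounters = 10, mode = "hazard",
                               event_prevalence = 1)),
    class = "detvalid_config_error"
  )
})

test_that("bias knobs validate their group names", {
  expect_error(sim_config(bias_knobs = list(planet = list(mars = list()))),
               class = "detvalid_config_error")
  expect_error(sim_config(bias_knobs = list(sex = list(unknown = list()))),
               class = "detvalid_config_error")
  sim <- simulate_cohort(sim_config(n_encounters = 10, seed = 1))
  expect_error(inject_subgroup_bias(sim, list(sex = list(unknown = list()))),
               class = "detvalid_config_error")
})

test_that("post-hoc score shift moves the group mean and leaves labels alone", {
  sim <- simulate_cohort(sim_config(n_encounters = 400, seed = 55))
  shifted <- inject_subgroup_bias(
    sim, list(sex = list(female = list(score_shift = -10))), seed = 2
  )
  # neutral knobs are the identity
  ident <- inject_subgroup_bias(sim, list(sex = list(female = list())), seed = 2)
  expect_identical(ident$predictions$score, sim$predictions$score)
  fem <- sim$encounters$encounter_id[sim$encounters$sex == "female"]
  sel <- sim$predictions$encounter_id %in% fem
  delta <- mean(shifted$predictions$score[sel]) - mean(sim$predictions$score[sel])
  expect_lt(abs(delta + 10), 0.5) # clipping at 0 is rare at these score levels
  expect_identical(shifted$events, sim$events)
  # untouched group unchanged
  expect_identical(shifted$predictions$score[!sel], sim$predictions$score[!sel])
})

test_that("post-hoc event-rate multiplier scales the group's prevalence", {
  sim <- simulate_cohort(sim_config(n_encounters = 4000, seed = 56))
  boosted <- inject_subgroup_bias(
    sim, list(sex = list(female = list(event_rate_multiplier = 2))), seed = 3
  )
  fem <- sim$encounters$encounter_id[sim$encounters$sex == "female"]
  before <- mean(fem %in% sim$events$encounter_id)
  after <- mean(fem %in% boosted$events$encounter_id)
  expect_lt(abs(after / before - 2), 0.25)
  # in-generator multiplier behaves the same way
  g <- simulate_cohort(sim_config(
    n_encounters = 4000, seed = 56,
    bias_knobs = list(sex = list(female = list(event_rate_multiplier = 2)))
  ))
  fem_g <- g$encounters$encounter_id[g$encounters$sex == "female"]
  mal_g <- g$encounters$encounter_id[g$encounters$sex == "male"]
  rate_f <- mean(fem_g %in% g$events$encounter_id)
  rate_m <- mean(mal_g %in% g$events$encounter_id)
  expect_lt(abs(rate_f / rate_m - 2), 0.4)
})
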