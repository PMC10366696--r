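# Independent oracles and small in-code fixtures used across the suite.
# These deliberately use the naive O(n^2) / scan formulations so they share
# no code path with the package implementations they check.

# AUROC by exhaustive pair counting: concordant + half of ties.
oracle_auroc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Average precision by the literal step sum over descending unique thresholds.
oracle_average_precision <- function(labels, scores) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_recall <- 0
  ap <- 0
  for (t in thresholds) {
    flagged <- scores >= t
    tp <- sum(flagged & labels == 1)
    precision <- tp / sum(flagged)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Window labels by a brute-force scan over every (prediction, event) pair.
oracle_window_labels <- function(pred_rel_min, event_rel_min_by_enc, pred_enc,
                                 lead_time_h) {
  out <- integer(length(pred_rel_min))
  for (i in seq_along(pred_rel_min)) {
    ev <- event_rel_min_by_enc[[pred_enc[i]]]
    if (is.null(ev) || is.na(ev)) next
    if (ev > pred_rel_min[i] && ev <= pred_rel_min[i] + lead_time_h * 60) {
      out[i] <- 1L
    }
  }
  out
}

# Closed-form Wilson interval written independently of the package version.
oracle_wilson <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n),
    (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n))
}

# --- toy cohort builders ------------------------------------------------

ts_at <- function(hours) {
  as.POSIXct("2021-03-01 00:00:00", tz = "UTC") + hours * 3600
}

# A hand-built six-encounter cohort exercising every exclusion rule.
make_toy_tables <- function() {
  encounters <- tibble::tibble(
    encounter_id = c("A", "B", "C", "D", "E", "F"),
    admission_ts = ts_at(0),
    discharge_ts = ts_at(c(48, 40, 50, 30, 32, 24)),
    age_years = c(70, 55, 80, 45, 60, 35),
    sex = c("female", "male", "female", "male", "female", "male"),
    race = c("White", "White", "Black or African American", "White",
             "Asian", "White"),
    ethnicity = "other ethnicity",
    code_status = "full",
    comfort_care_ts = ts_at(c(NA, NA, 47, NA, NA, NA))
  )
  predictions <- tibble::tibble(
    encounter_id = c("A", "A", "A",
                     "B", "B", "B",
                     "C", "C",
                     "D", "D",
                     "E",
                     "F", "F"),
    ts = ts_at(c(1, 10, 20,
                 10, 29, 31,
                 5, 20,
                 2, 10,
                 31,
                 1, 2)),
    score = c(10, 55, 40,
              20, 60, 80,
              15, 30,
              25, 35,
              50,
              45, 20),
    location_class = c("ward", "ward", "ward",
                       "ward", "ward", "ward",
                       "ward", "ward",
                       "ward", "ward",
                       "ward",
                       "icu", "preop")
  )
  events <- tibble::tibble(
    encounter_id = c("B", "C", "E"),
    event_type = c("icu_transfer", "death", "icu_transfer"),
    ts = ts_at(c(30, 50, 30))
  )
  list(encounters = encounters, predictions = predictions, events = events)
}

make_toy_analysis_set <- function() {
  tt <- make_toy_tables()
  build_analysis_set(parse_cohort(tt$encounters, tt$predictions, tt$events))
}

# Random labeled instance with ties for metric property tests.
random_instance <- function(n) {
  labels <- rbinom(n, 1, runif(1, 0.15, 0.6))
  if (sum(labels) == 0) labels[sample(n, 1)] <- 1L
  if (sum(labels) == n) labels[sample(n, 1)] <- 0L
  # coarse grid => plenty of ties
  scores <- sample(seq(0, 100, by = 5), n, replace = TRUE) +
    sample(c(0, 0, 0.5), n, replace = TRUE)
  list(labels = labels, scores = scores)
}
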