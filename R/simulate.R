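# Synthetic hospital-cohort generator with known ground truth. Two modes:
#   * binormal — analytically tractable: scores within the label horizon of an
#     event are drawn from the positive class-conditional (truncated) normal,
#     all others from the negative one, so the population observation-level
#     AUROC has the closed form of theoretical_auroc();
#   * hazard — a realistic stream: a latent per-encounter severity drives an
#     event hazard and a noisy score with a warning signal that decays with
#     distance to the event.
# Per-encounter RNG substreams keep encounter i's draws identical whatever
# the total cohort size under the same master seed.

#' Simulation configuration for the synthetic cohort generator
#'
#' Defaults emulate the cohort the evaluation is designed for: adult
#' hospitalizations scored every 15 minutes, roughly 10% encounter-level
#' deterioration prevalence, length of stay lognormal with median about
#' 3.1 days, deterioration concentrated tens of hours after presentation
#' (median about 68 h), demographic mixes typical of a Midwestern US health
#' system, and ICU transfers flipping subsequent care locations to `icu` so
#' the location exclusions are exercised.
#'
#' @param n_encounters Number of encounters to simulate.
#' @param seed Master integer seed; one seed, one output.
#' @param score_interval_min Score cadence in minutes (default 15).
#' @param los_meanlog,los_sdlog Lognormal length-of-stay parameters (days).
#' @param event_prevalence Target encounter-level deterioration prevalence.
#' @param mode `"binormal"` or `"hazard"`.
#' @param binormal_params List: `mu_neg`, `mu_pos`, `sigma_neg`, `sigma_pos`
#'   on the 0-100 score scale, and `label_horizon_h` (hours before the event
#'   during which scores are drawn from the positive class).
#' @param hazard_params List: `baseline_hazard` (per hour; `NULL` calibrates
#'   it to `event_prevalence`), `severity_link` (log-hazard per severity SD),
#'   `score_base`, `score_sd`, `severity_score_gain`, `signal_amplitude`.
#' @param signal_decay_per_hour Exponential decay rate of the pre-event
#'   warning signal (hazard mode).
#' @param event_time_meanlog,event_time_sdlog Lognormal admission-to-event
#'   time parameters, hours (binormal mode).
#' @param post_event_los_meanlog,post_event_los_sdlog Lognormal extra stay
#'   after a non-fatal event, hours.
#' @param event_type_freq Named frequencies over the three event types.
#' @param comfort_care_rate Fraction of encounters carrying a comfort-care
#'   order timestamp.
#' @param preop_prefix_rate Fraction of encounters whose first scores are in
#'   a perioperative location.
#' @param sex_freq,race_freq,ethnicity_freq,code_status_freq Named category
#'   frequencies (must each sum to 1).
#' @param age_mean,age_sd,age_min Age distribution (normal truncated below
#'   at `age_min`).
#' @param bias_knobs Optional per-group effects, a nested list
#'   `list(axis = list(category = list(score_shift =, event_rate_multiplier =,
#'   signal_mask_rate =)))`. `signal_mask_rate` is the fraction of the
#'   group's event encounters whose scores are drawn from the no-event
#'   distribution (a direct multiplicative sensitivity deficit).
#' @return A `dti_sim_config` list.
#' @export
sim_config <- function(n_encounters = 1000,
                       seed = 1L,
                       score_interval_min = 15,
                       los_meanlog = log(3.1), los_sdlog = 0.69,
                       event_prevalence = 0.103,
                       mode = c("binormal", "hazard"),
                       binormal_params = list(),
                       hazard_params = list(),
                       signal_decay_per_hour = 0.05,
                       event_time_meanlog = log(68), event_time_sdlog = 0.76,
                       post_event_los_meanlog = log(59), post_event_los_sdlog = 0.8,
                       event_type_freq = c(mechanical_ventilation = 0.25,
                                           icu_transfer = 0.60, death = 0.15),
                       comfort_care_rate = 0.02,
                       preop_prefix_rate = 0.05,
                       sex_freq = c(female = 0.549, male = 0.451),
                       race_freq = c("White" = 0.815,
                                     "Black or African American" = 0.090,
                                     "Asian" = 0.031,
                                     "American Indian or Alaska Native" = 0.018,
                                     "chose-not-to-answer" = 0.041,
                                     "Middle Eastern or North African" = 0.001,
                                     "Native Hawaiian or other Pacific Islander" = 0.002,
                                     "missing" = 0.002),
                       ethnicity_freq = c("Hispanic or Latino" = 0.018,
                                          "other ethnicity" = 0.890,
                                          "chose-not-to-answer" = 0.092),
                       code_status_freq = c(full = 0.866, DNR = 0.100,
                                            missing = 0.034),
                       age_mean = 60.3, age_sd = 19.2, age_min = 18,
                       bias_knobs = NULL) {
  mode <- match.arg(mode)
  bn_default <- list(mu_neg = 35, mu_pos = 35 + 12 * sqrt(2),
                     sigma_neg = 12, sigma_pos = 12, label_horizon_h = 12)
  hz_default <- list(baseline_hazard = NULL, severity_link = 0.8,
                     score_base = 30, score_sd = 10,
                     severity_score_gain = 6, signal_amplitude = 35)
  binormal_params <- utils::modifyList(bn_default, binormal_params)
  hazard_params <- utils::modifyList(hz_default, hazard_params)

  for (nm in c("sex_freq", "race_freq", "ethnicity_freq", "code_status_freq",
               "event_type_freq")) {
    f <- get(nm)
    if (abs(sum(f) - 1) > 1e-6) {
      abort_config(sprintf("%s frequencies must sum to 1 (got %.4f)", nm, sum(f)))
    }
  }
  if (mode == "binormal" && (event_prevalence < 0 || event_prevalence > 1)) {
    abort_config("event_prevalence must lie in [0,1] (achievable range 0-1)")
  }
  if (!is.null(bias_knobs)) {
    valid_groups <- list(sex = names(sex_freq), race = names(race_freq),
                         ethnicity = names(ethnicity_freq),
                         age = c("under_60", "60_and_over"))
    for (axis in names(bias_knobs)) {
      if (!axis %in% names(valid_groups)) {
        abort_config(sprintf("bias knob for unknown axis '%s'", axis))
      }
      bad <- setdiff(names(bias_knobs[[axis]]), valid_groups[[axis]])
      if (length(bad)) {
        abort_config(sprintf("bias knob for unknown %s group(s): %s",
                             axis, paste(bad, collapse = ", ")))
      }
    }
  }

  structure(
    list(n_encounters = n_encounters, seed = as.integer(seed),
         score_interval_min = score_interval_min,
         los_meanlog = los_meanlog, los_sdlog = los_sdlog,
         event_prevalence = event_prevalence, mode = mode,
         binormal_params = binormal_params, hazard_params = hazard_params,
         signal_decay_per_hour = signal_decay_per_hour,
         event_time_meanlog = event_time_meanlog,
         event_time_sdlog = event_time_sdlog,
         post_event_los_meanlog = post_event_los_meanlog,
         post_event_los_sdlog = post_event_los_sdlog,
         event_type_freq = event_type_freq,
         comfort_care_rate = comfort_care_rate,
         preop_prefix_rate = preop_prefix_rate,
         sex_freq = sex_freq, race_freq = race_freq,
         ethnicity_freq = ethnicity_freq, code_status_freq = code_status_freq,
         age_mean = age_mean, age_sd = age_sd, age_min = age_min,
         bias_knobs = bias_knobs),
    class = "dti_sim_config"
  )
}

#' Closed-form binormal AUROC
#'
#' For scores drawn from N(mu_neg, sigma_neg^2) in the negative class and
#' N(mu_pos, sigma_pos^2) in the positive class, the population AUROC is
#' `pnorm((mu_pos - mu_neg) / sqrt(sigma_neg^2 + sigma_pos^2))`. A warning
#' flags configurations where more than 1% of either class's mass is
#' truncated by the \[0,100\] score bounds, which degrades the identity.
#'
#' @param mu_neg,mu_pos Class means on the 0-100 scale.
#' @param sigma_neg,sigma_pos Class standard deviations (> 0).
#' @return AUROC in (0,1).
#' @export
theoretical_auroc <- function(mu_neg, mu_pos, sigma_neg, sigma_pos) {
  if (sigma_neg <= 0 || sigma_pos <= 0) abort_config("sigmas must be positive")
  trunc_mass <- max(
    stats::pnorm(0, mu_neg, sigma_neg) + stats::pnorm(100, mu_neg, sigma_neg,
                                                      lower.tail = FALSE),
    stats::pnorm(0, mu_pos, sigma_pos) + stats::pnorm(100, mu_pos, sigma_pos,
                                                      lower.tail = FALSE)
  )
  if (trunc_mass > 0.01) {
    rlang::warn(sprintf(
      "more than 1%% of class mass truncated at [0,100] (%.1f%%); closed form is approximate",
      100 * trunc_mass
    ))
  }
  stats::pnorm((mu_pos - mu_neg) / sqrt(sigma_neg^2 + sigma_pos^2))
}

# Truncated-normal sampler on [lo, hi] via inverse CDF.
rtnorm <- function(n, mu, sigma, lo = 0, hi = 100) {
  if (n == 0) return(numeric(0))
  a <- stats::pnorm((lo - mu) / sigma)
  b <- stats::pnorm((hi - mu) / sigma)
  mu + sigma * stats::qnorm(stats::runif(n, a, b))
}

# Calibrate the hazard-mode baseline so expected prevalence hits the target.
calibrate_hazard_baseline <- function(config) {
  b <- config$hazard_params$severity_link
  zg <- stats::qnorm(stats::ppoints(101))
  los_h <- stats::qlnorm(stats::ppoints(101), config$los_meanlog,
                         config$los_sdlog) * 24
  grid <- expand.grid(z = zg, los = los_h)
  f <- function(h) mean(1 - exp(-h * exp(b * grid$z) * grid$los)) -
    config$event_prevalence
  hi <- 10
  if (f(hi) < 0) {
    abort_config(sprintf(
      "prevalence target %.3f not achievable; achievable range is (0, %.3f] for baseline hazard <= %g/h",
      config$event_prevalence, f(hi) + config$event_prevalence, hi
    ))
  }
  stats::uniroot(f, lower = 1e-8, upper = hi, tol = 1e-10)$root
}

knob_for <- function(knobs, axis, value) {
  if (is.null(knobs) || is.null(knobs[[axis]])) return(NULL)
  knobs[[axis]][[value]]
}

# Combined bias-knob effect for one encounter's demographics.
combined_knobs <- function(knobs, sex, race, ethnicity, age) {
  eff <- list(score_shift = 0, event_rate_multiplier = 1, signal_mask_rate = 0)
  if (is.null(knobs)) return(eff)
  vals <- list(sex = sex, race = race, ethnicity = ethnicity,
               age = if (age < 60) "under_60" else "60_and_over")
  for (axis in names(vals)) {
    k <- knob_for(knobs, axis, vals[[axis]])
    if (is.null(k)) next
    eff$score_shift <- eff$score_shift + (k$score_shift %||% 0)
    eff$event_rate_multiplier <- eff$event_rate_multiplier *
      (k$event_rate_multiplier %||% 1)
    eff$signal_mask_rate <- max(eff$signal_mask_rate, k$signal_mask_rate %||% 0)
  }
  eff
}

#' Simulate a hospital cohort with known ground truth
#'
#' Generates the three tables [parse_cohort()] reads — encounters,
#' predictions (one score every `score_interval_min` minutes from admission
#' to discharge), events — under the configured generative model. Death
#' events are placed exactly at discharge; ICU transfers flip subsequent
#' location labels to `icu`; a configurable fraction of encounters starts in
#' a perioperative location and a fraction carries a comfort-care order, so
#' every exclusion rule downstream is exercised. Identical seeds give
#' identical output, and per-encounter RNG substreams make encounter `i`'s
#' data invariant to the total cohort size.
#'
#' @param config A [sim_config()].
#' @return A `dti_sim_cohort` list: tibbles `encounters`, `predictions`,
#'   `events`, and `ground_truth` (the config, the closed-form AUROC in
#'   binormal mode, realized prevalence, masked encounter ids).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "dti_sim_config"))
  n <- config$n_encounters
  interval <- config$score_interval_min
  mode <- config$mode
  bp <- config$binormal_params
  hp <- config$hazard_params
  horizon_min <- bp$label_horizon_h * 60

  baseline_h <- NULL
  if (mode == "hazard") {
    baseline_h <- hp$baseline_hazard %||% calibrate_hazard_baseline(config)
  }

  base_adm <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
  admission <- base_adm + (((seq_len(n) - 1) * 193) %% (150 * 1440)) * 60

  sex <- race <- ethnicity <- code_status <- character(n)
  age <- numeric(n)
  has_event <- logical(n)
  masked <- logical(n)
  event_min <- rep(NA_real_, n)
  event_type <- rep(NA_character_, n)
  discharge_min <- numeric(n)
  cc_min <- rep(NA_real_, n)

  t_list <- vector("list", n)
  score_list <- vector("list", n)
  loc_list <- vector("list", n)

  draw_cat <- function(freq) sample(names(freq), 1, prob = freq)

  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))

    sex[i] <- draw_cat(config$sex_freq)
    race[i] <- draw_cat(config$race_freq)
    ethnicity[i] <- draw_cat(config$ethnicity_freq)
    code_status[i] <- draw_cat(config$code_status_freq)
    u <- stats::runif(1, stats::pnorm((config$age_min - config$age_mean) /
                                        config$age_sd), 1)
    age[i] <- config$age_mean + config$age_sd * stats::qnorm(u)

    eff <- combined_knobs(config$bias_knobs, sex[i], race[i], ethnicity[i], age[i])

    if (mode == "binormal") {
      p_event <- min(config$event_prevalence * eff$event_rate_multiplier, 0.98)
      has_event[i] <- stats::runif(1) < p_event
      z <- NA_real_
    } else {
      z <- stats::rnorm(1)
      rate <- baseline_h * exp(hp$severity_link * z) * eff$event_rate_multiplier
      T_exp_h <- if (rate > 0) stats::rexp(1, rate) else Inf
    }

    los_min <- max(round(stats::rlnorm(1, config$los_meanlog,
                                       config$los_sdlog) * 1440), 120)

    if (mode == "hazard") {
      has_event[i] <- is.finite(T_exp_h) && (T_exp_h * 60) < los_min
      if (has_event[i]) event_min[i] <- max(round(T_exp_h * 60), 30)
    } else if (has_event[i]) {
      event_min[i] <- max(round(stats::rlnorm(1, config$event_time_meanlog,
                                              config$event_time_sdlog) * 60), 30)
    }

    if (has_event[i]) {
      event_type[i] <- draw_cat(config$event_type_freq)
      if (event_type[i] == "death") {
        discharge_min[i] <- event_min[i]
      } else {
        extra <- max(round(stats::rlnorm(1, config$post_event_los_meanlog,
                                         config$post_event_los_sdlog) * 60),
                     interval)
        discharge_min[i] <- event_min[i] + extra
      }
      masked[i] <- eff$signal_mask_rate > 0 &&
        stats::runif(1) < eff$signal_mask_rate
    } else {
      discharge_min[i] <- los_min
    }

    if (stats::runif(1) < config$comfort_care_rate) {
      cc_min[i] <- if (has_event[i]) {
        min(max(round(event_min[i] * stats::runif(1, 0.6, 1.4)), 15),
            discharge_min[i])
      } else {
        max(round(discharge_min[i] * stats::runif(1, 0.5, 1)), 15)
      }
    }

    t <- seq(0, discharge_min[i], by = interval)
    m <- length(t)

    loc <- rep("ward", m)
    if (stats::runif(1) < config$preop_prefix_rate) {
      k <- min(8L, m)
      loc[seq_len(k)] <- if (i %% 2 == 0) "preop" else "intraop"
    }
    if (has_event[i] && event_type[i] == "icu_transfer") {
      loc[t >= event_min[i]] <- "icu"
    }

    if (mode == "binormal") {
      pos <- has_event[i] && !masked[i]
      in_window <- if (pos) {
        tte <- event_min[i] - t
        tte > 0 & tte <= horizon_min
      } else rep(FALSE, m)
      sc <- numeric(m)
      sc[!in_window] <- rtnorm(sum(!in_window), bp$mu_neg, bp$sigma_neg)
      sc[in_window] <- rtnorm(sum(in_window), bp$mu_pos, bp$sigma_pos)
    } else {
      sig <- rep(0, m)
      if (has_event[i] && !masked[i]) {
        pre <- t < event_min[i]
        sig[pre] <- hp$signal_amplitude *
          exp(-config$signal_decay_per_hour * (event_min[i] - t[pre]) / 60)
      }
      sc <- hp$score_base + hp$severity_score_gain * z + sig +
        stats::rnorm(m, 0, hp$score_sd)
    }
    sc <- pmin(pmax(sc + eff$score_shift, 0), 100)

    t_list[[i]] <- t
    score_list[[i]] <- sc
    loc_list[[i]] <- loc
  }

  enc_id <- sprintf("E%06d", seq_len(n))
  n_obs <- lengths(t_list)

  encounters <- tibble::tibble(
    encounter_id = enc_id,
    patient_id = sprintf("P%06d", seq_len(n)),
    hospital_id = sprintf("H%d", (seq_len(n) %% 8) + 1),
    admission_ts = admission,
    discharge_ts = admission + discharge_min * 60,
    age_years = age, sex = sex, race = race, ethnicity = ethnicity,
    code_status = code_status,
    comfort_care_ts = admission + cc_min * 60
  )

  predictions <- tibble::tibble(
    encounter_id = rep(enc_id, n_obs),
    ts = rep(admission, n_obs) + unlist(t_list, use.names = FALSE) * 60,
    score = unlist(score_list, use.names = FALSE),
    location_class = unlist(loc_list, use.names = FALSE)
  )

  ev <- which(has_event)
  events <- tibble::tibble(
    encounter_id = enc_id[ev],
    event_type = event_type[ev],
    ts = admission[ev] + event_min[ev] * 60
  )

  gt <- list(
    config = config,
    realized_prevalence = mean(has_event),
    masked_encounters = enc_id[masked],
    hazard_baseline = baseline_h
  )
  if (mode == "binormal") {
    gt$theoretical_auroc <- theoretical_auroc(bp$mu_neg, bp$mu_pos,
                                              bp$sigma_neg, bp$sigma_pos)
  }

  structure(
    list(encounters = encounters, predictions = predictions, events = events,
         ground_truth = gt),
    class = "dti_sim_cohort"
  )
}

#' Apply subgroup bias effects to an already-simulated cohort
#'
#' Post-hoc application of per-group effects to the three tables:
#' `score_shift` adds a constant to the group's scores (clipped to
#' \[0,100\]; labels untouched); `event_rate_multiplier` greater than 1
#' promotes a matching number of the group's event-free encounters to
#' non-fatal deterioration events (at a lognormally drawn time inside the
#' stay, scores unchanged), and a multiplier below 1 removes events from the
#' sampled fraction of the group's event encounters. The injected ground
#' truth is recorded in the `injected_bias` attribute.
#'
#' @param tables A `dti_sim_cohort` or plain list with `encounters`,
#'   `predictions`, `events` tibbles.
#' @param bias_knobs Nested list as in [sim_config()].
#' @param seed Seed for the sampling steps.
#' @return The modified tables, same shape as the input.
#' @export
inject_subgroup_bias <- function(tables, bias_knobs, seed = 1L) {
  enc <- tables$encounters
  prd <- tables$predictions
  evt <- tables$events
  set.seed(seed)

  group_ids <- function(axis, value) {
    if (axis == "age") {
      v <- ifelse(enc$age_years < 60, "under_60", "60_and_over")
    } else if (axis %in% names(enc)) {
      v <- as.character(enc[[axis]])
    } else {
      abort_config(sprintf("bias knob for unknown axis '%s'", axis))
    }
    if (axis != "age" && !value %in% v) {
      abort_config(sprintf("bias knob for unknown %s group '%s'", axis, value))
    }
    enc$encounter_id[v == value]
  }

  for (axis in names(bias_knobs)) {
    for (value in names(bias_knobs[[axis]])) {
      k <- bias_knobs[[axis]][[value]]
      ids <- group_ids(axis, value)

      shift <- k$score_shift %||% 0
      if (shift != 0) {
        sel <- prd$encounter_id %in% ids
        prd$score[sel] <- pmin(pmax(prd$score[sel] + shift, 0), 100)
      }

      mult <- k$event_rate_multiplier %||% 1
      if (mult != 1) {
        ev_ids <- intersect(ids, unique(evt$encounter_id))
        if (mult < 1) {
          drop_n <- round((1 - mult) * length(ev_ids))
          drop <- sample(ev_ids, drop_n)
          evt <- evt[!evt$encounter_id %in% drop, , drop = FALSE]
        } else {
          free <- setdiff(ids, ev_ids)
          add_n <- min(round((mult - 1) * length(ev_ids)), length(free))
          add <- sample(free, add_n)
          if (length(add)) {
            e <- enc[match(add, enc$encounter_id), ]
            span_min <- minutes_between(e$admission_ts, e$discharge_ts)
            frac <- stats::runif(length(add), 0.2, 0.9)
            new_ev <- tibble::tibble(
              encounter_id = add,
              event_type = sample(c("mechanical_ventilation", "icu_transfer"),
                                  length(add), replace = TRUE,
                                  prob = c(0.3, 0.7)),
              ts = e$admission_ts + round(span_min * frac) * 60
            )
            evt <- dplyr::bind_rows(evt, new_ev)
          }
        }
      }
    }
  }

  out <- tables
  out$encounters <- enc
  out$predictions <- prd
  out$events <- evt
  attr(out, "injected_bias") <- bias_knobs
  out
}

#' Write a simulated cohort to CSV (or Parquet) files
#'
#' Emits the same schemas [parse_cohort()] reads, plus a ground-truth JSON
#' (true parameters and closed-form metrics).
#'
#' @param sim A `dti_sim_cohort`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (default) or `"parquet"`.
#' @return Invisibly, the named vector of file paths.
#' @export
write_sim_cohort <- function(sim, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(encounters = file.path(dir, paste0("encounters.", format)),
             predictions = file.path(dir, paste0("predictions.", format)),
             events = file.path(dir, paste0("events.", format)),
             ground_truth = file.path(dir, "ground_truth.json"))
  for (nm in c("encounters", "predictions", "events")) {
    if (format == "csv") {
      readr::write_csv(sim[[nm]], paths[[nm]])
    } else {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        abort_schema("writing Parquet requires the 'arrow' package")
      }
      arrow::write_parquet(sim[[nm]], paths[[nm]])
    }
  }
  gt <- sim$ground_truth
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, paths[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}
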