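# Orchestration: one call that runs ingest -> labeling -> lead-time grid ->
# overall curve metrics -> calibration -> threshold suite -> bias audit and
# writes a reproducible report bundle (CSV tables + JSON summary + exclusion
# ledger + status manifest). Every stochastic step is seeded from the config.

#' Build a validation run configuration
#'
#' Either supply the three input tables (paths or data frames) or set
#' `simulate = TRUE` with a [sim_config()]. Can also be loaded from a YAML
#' file with [read_validation_config()].
#'
#' @param encounters,predictions,events Input tables or file paths (ignored
#'   when `simulate = TRUE`).
#' @param simulate Generate the inputs with [simulate_cohort()]?
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param lead_times_h Lead-time grid in hours (positive, sorted).
#' @param headline_lead_time_h Observation-level headline setting (default
#'   12 h) used for calibration and threshold selection.
#' @param target_sensitivity Medium-risk sensitivity target (default 0.50).
#' @param target_ppv High-risk PPV target (default 0.10).
#' @param n_bins Calibration bins (default 20).
#' @param bootstrap_ci Compute bootstrap CIs for AUROC/AUPRC?
#' @param bootstrap_B Bootstrap replicates (default 1000).
#' @param seed Master seed for all stochastic steps.
#' @param subgroup_axes Axes for the parity audit.
#' @param excluded_locations,minimum_age Cohort exclusion settings.
#' @param out_dir Output directory for the report bundle.
#' @return A `dti_run_config` list.
#' @export
validation_config <- function(encounters = NULL, predictions = NULL, events = NULL,
                              simulate = FALSE, sim = sim_config(),
                              lead_times_h = c(3, 6, 12, 24, 38, 72),
                              headline_lead_time_h = 12,
                              target_sensitivity = 0.50, target_ppv = 0.10,
                              n_bins = 20,
                              bootstrap_ci = FALSE, bootstrap_B = 1000,
                              seed = 1L,
                              subgroup_axes = BIAS_AXES,
                              excluded_locations = DEFAULT_EXCLUDED_LOCATIONS,
                              minimum_age = 18,
                              out_dir = NULL) {
  if (!length(lead_times_h)) abort_config("lead_times_h must be non-empty")
  if (any(lead_times_h <= 0)) abort_config("lead times must be positive")
  if (is.unsorted(lead_times_h)) abort_config("lead times must be sorted increasing")
  for (t in c(target_sensitivity, target_ppv)) {
    if (t <= 0 || t >= 1) abort_config("targets must lie in (0,1)")
  }
  if (!simulate && (is.null(encounters) || is.null(predictions) || is.null(events))) {
    abort_config("either supply the three input tables or set simulate = TRUE")
  }
  structure(
    list(encounters = encounters, predictions = predictions, events = events,
         simulate = simulate, sim = sim,
         lead_times_h = lead_times_h,
         headline_lead_time_h = headline_lead_time_h,
         target_sensitivity = target_sensitivity, target_ppv = target_ppv,
         n_bins = n_bins, bootstrap_ci = bootstrap_ci, bootstrap_B = bootstrap_B,
         seed = as.integer(seed), subgroup_axes = subgroup_axes,
         excluded_locations = excluded_locations, minimum_age = minimum_age,
         out_dir = out_dir),
    class = "dti_run_config"
  )
}

#' Read a validation configuration from YAML
#'
#' Recognized keys mirror the [validation_config()] arguments; `sim` keys are
#' passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A `dti_run_config`.
#' @export
read_validation_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  args <- y
  args$sim <- do.call(sim_config, sim_args)
  do.call(validation_config, args)
}

op_to_list <- function(op) {
  list(threshold = op$threshold,
       tp = op$tp, fp = op$fp, tn = op$tn, fn = op$fn,
       sensitivity = as.list(op$sensitivity),
       specificity = as.list(op$specificity),
       ppv = as.list(op$ppv), npv = as.list(op$npv),
       f1 = as.list(op$f1), nne = as.list(op$nne),
       rule = op$rule %||% NA, target = op$target %||% NA,
       attained = op$attained %||% NA)
}

#' Run the full validation pipeline and write a report bundle
#'
#' Executes ingest, labeling, the lead-time grid, overall observation- and
#' encounter-level discrimination, calibration, the threshold suite and the
#' subgroup bias audit, and writes to `config$out_dir`: the exclusion ledger
#' (JSON), a cohort characteristics table, the lead-time grid, the threshold
#' table, the parity table, the calibration table (CSV), a machine-readable
#' `summary.json`, and a `manifest.json` naming the status of every stage.
#' A stage failure produces a partial bundle with the failed stage named in
#' the manifest rather than an error.
#'
#' @param config A `dti_run_config`.
#' @return Invisibly, a `dti_report_bundle` list with all computed objects
#'   and the output paths.
#' @export
run_full_validation <- function(config) {
  stopifnot(inherits(config, "dti_run_config"))
  out_dir <- config$out_dir %||% tempfile("detvalid_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  bundle <- list(config = config, out_dir = out_dir)
  manifest <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(list(ok = TRUE, value = force(expr)),
                    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    manifest[[name]] <<- if (res$ok) "ok" else paste("failed:", res$error)
    if (res$ok) res$value else NULL
  }

  inputs <- run_stage("inputs", {
    if (config$simulate) {
      sim <- simulate_cohort(config$sim)
      bundle$ground_truth <- sim$ground_truth
      sim
    } else {
      list(encounters = config$encounters, predictions = config$predictions,
           events = config$events)
    }
  })

  aset <- run_stage("ingest", {
    cohort <- parse_cohort(inputs$encounters, inputs$predictions, inputs$events)
    build_analysis_set(cohort,
                       excluded_locations = config$excluded_locations,
                       minimum_age = config$minimum_age)
  })
  if (is.null(aset)) {
    return(finalize_bundle(bundle, manifest))
  }
  bundle$analysis_set <- aset
  bundle$cohort_summary <- run_stage("describe", describe_cohort(aset))

  headline <- run_stage("labeling", {
    label_observation_level(aset, config$headline_lead_time_h, "composite")
  })
  enc_summ <- run_stage("encounter_level", summarize_encounter_level(aset))

  bundle$observation_metrics <- run_stage("observation_metrics", {
    curve_metrics(headline$label, headline$score,
                  ci = config$bootstrap_ci, B = config$bootstrap_B,
                  seed = config$seed, cluster = headline$encounter_id)
  })
  bundle$encounter_metrics <- run_stage("encounter_metrics", {
    curve_metrics(enc_summ$label, enc_summ$max_score,
                  ci = config$bootstrap_ci, B = config$bootstrap_B,
                  seed = config$seed + 1)
  })

  bundle$lead_time_grid <- run_stage("lead_time_sweep", {
    lead_time_sweep(aset, config$lead_times_h)
  })

  bundle$calibration <- run_stage("calibration", {
    calibration_table(headline$label, headline$score / 100, config$n_bins)
  })

  bundle$threshold_suite <- run_stage("thresholds", {
    threshold_suite(headline$label, headline$score,
                    target_sensitivity = config$target_sensitivity,
                    target_ppv = config$target_ppv)
  })

  bundle$parity <- run_stage("bias_audit", {
    thr <- max_f1_threshold(enc_summ$label, enc_summ$max_score)$threshold
    audit_all_subgroups(enc_summ, thr, axes = config$subgroup_axes)
  })

  finalize_bundle(bundle, manifest)
}

finalize_bundle <- function(bundle, manifest) {
  out_dir <- bundle$out_dir
  w_csv <- function(x, name) {
    if (!is.null(x)) readr::write_csv(x, file.path(out_dir, name))
  }

  if (!is.null(bundle$analysis_set)) {
    jsonlite::write_json(bundle$analysis_set$exclusion_ledger,
                         file.path(out_dir, "exclusion_ledger.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    w_csv(bundle$cohort_summary$characteristics, "cohort_characteristics.csv")
    w_csv(bundle$cohort_summary$durations, "cohort_durations.csv")
  }
  if (!is.null(bundle$lead_time_grid)) {
    w_csv(tibble::as_tibble(bundle$lead_time_grid), "lead_time_grid.csv")
    w_csv(render_lead_time_grid(bundle$lead_time_grid), "lead_time_grid_wide.csv")
  }
  if (!is.null(bundle$threshold_suite)) {
    w_csv(render_threshold_suite(bundle$threshold_suite), "threshold_table.csv")
  }
  w_csv(bundle$parity, "parity_table.csv")
  w_csv(bundle$calibration, "calibration_table.csv")

  summary <- list(
    settings = list(
      lead_times_h = bundle$config$lead_times_h,
      headline_lead_time_h = bundle$config$headline_lead_time_h,
      target_sensitivity = bundle$config$target_sensitivity,
      target_ppv = bundle$config$target_ppv,
      n_bins = bundle$config$n_bins,
      seed = bundle$config$seed,
      simulate = bundle$config$simulate,
      excluded_locations = bundle$config$excluded_locations,
      minimum_age = bundle$config$minimum_age
    )
  )
  if (!is.null(bundle$cohort_summary)) {
    summary$cohort <- list(
      n_encounters = bundle$cohort_summary$n_encounters,
      n_deterioration = bundle$cohort_summary$n_deterioration,
      prevalence_pct = bundle$cohort_summary$prevalence_pct
    )
  }
  cm_list <- function(cm) {
    if (is.null(cm)) return(NULL)
    list(auroc = cm$auroc, auroc_ci = as.list(cm$auroc_ci),
         auprc = cm$auprc, auprc_ci = as.list(cm$auprc_ci),
         n_pos = cm$n_pos, n_neg = cm$n_neg)
  }
  summary$observation_level <- cm_list(bundle$observation_metrics)
  summary$encounter_level <- cm_list(bundle$encounter_metrics)
  if (!is.null(bundle$threshold_suite)) {
    summary$thresholds <- list(
      medium = op_to_list(bundle$threshold_suite$medium),
      single = op_to_list(bundle$threshold_suite$single),
      high = op_to_list(bundle$threshold_suite$high)
    )
  }
  if (!is.null(bundle$ground_truth)) {
    summary$ground_truth <- list(
      theoretical_auroc = bundle$ground_truth$theoretical_auroc,
      realized_prevalence = bundle$ground_truth$realized_prevalence
    )
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  bundle$manifest <- manifest
  bundle$summary <- summary
  class(bundle) <- "dti_report_bundle"
  invisible(bundle)
}

#' @export
print.dti_report_bundle <- function(x, ...) {
  cat("<dti_report_bundle> at", x$out_dir, "\n")
  for (nm in names(x$manifest)) {
    cat(sprintf("  %-20s %s\n", nm, x$manifest[[nm]]))
  }
  invisible(x)
}
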