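# detvalid

Validation and fairness auditing of continuous inpatient deterioration risk
scores.

## The problem

Hospitals increasingly run machine-learned early-warning models that emit a
probabilistic deterioration score in [0, 100] for every inpatient on a fixed
cadence (typically every 15 minutes). Before such a score stream can drive
alerts, it has to be validated against what actually happened: did the
patient go on to mechanical ventilation, ICU transfer, or death (timestamped
at discharge)? `detvalid` implements that validation end to end for *any*
score stream, treating the model itself as a black box:

* **Cohort assembly** with auditable exclusions: scores produced in
  preoperative, intraoperative, ICU, or labor-and-delivery locations are
  removed; encounters in which a comfort-care order precedes deterioration
  are removed whole; scores at or after the first deterioration event are
  removed (a score concurrent with deterioration offers no warning). Every
  removal is counted in an exclusion ledger.
* **Two evaluation levels.** Observation level: every score is a unit and
  its label asks whether the composite outcome occurs within a lead-time
  window `(t, t + L]` after it. Encounter level: one unit per
  hospitalization — the maximum pre-event score — labeled by whether
  deterioration ever occurred.
* **Discrimination and calibration.** AUROC (rank-sum estimator,
  `P(score_pos > score_neg)` with ties counting one half), average precision
  (recall-increment-weighted mean of precision), Wilson score intervals for
  proportions, seeded percentile bootstrap (optionally clustered by
  encounter) for curve metrics, and 20-bin calibration tables.
* **Lead-time sweeps** over horizons of 3, 6, 12, 24, 38 and 72 hours for
  the composite outcome and each component event.
* **Threshold selection with alert burden.** A medium-risk threshold
  targeting 50% sensitivity, a high-risk threshold targeting 10% PPV, and a
  single threshold maximizing F1 — each reported with the number needed to
  evaluate, NNE = 1/PPV: how many flagged predictions must be reviewed to
  find one true positive.
* **Subgroup parity audit** at the encounter level: AUROC parity,
  sensitivity parity (equal opportunity) and PPV parity — each the ratio of
  the protected group's metric to the reference group's (reference: White
  race, other ethnicity, male sex, age 60+) — plus the combined deviation
  `100 · (sum of parities / 3 − 1)`.
* **A seeded synthetic cohort generator** with known ground truth (closed
  form AUROC in binormal mode, decaying warning signal in hazard mode,
  injectable subgroup bias) so that every stage is testable against truth.

## Worked example

A small synthetic fixture ships with the package (12 encounters, hourly
scores, three deterioration events, one comfort-care exclusion):

```r
library(detvalid)
fx <- function(x) system.file("extdata", x, package = "detvalid")
cohort <- parse_cohort(fx("synthetic_encounters.csv"),
                       fx("synthetic_predictions.csv"),
                       fx("synthetic_events.csv"))
aset <- build_analysis_set(cohort)
print(aset)
#> <dti_analysis_set>
#>   encounters : 11 (of 12 input)
#>   predictions: 541 (of 670 input)
#>   deteriorations: 3 encounters
#>   exclusion ledger:
#>     age_below_minimum            encounter  removed      0, remaining     12
#>     age_below_minimum            prediction removed      0, remaining    670
#>     location_exclusion           prediction removed     46, remaining    624
#>     comfort_care_before_event    encounter  removed      1, remaining     11
#>     comfort_care_before_event    prediction removed     41, remaining    583
#>     post_event_prediction        prediction removed     42, remaining    541
#>     no_remaining_predictions     encounter  removed      0, remaining     11
```

The ledger is the machine-readable twin of a patient-selection flowchart:
46 perioperative/ICU scores, one whole encounter whose comfort-care order
preceded death (41 scores), and 42 post-event scores were removed, leaving
541 analyzable observations on 11 encounters.

```r
obs <- label_observation_level(aset, lead_time_h = 12)
cm <- curve_metrics(obs$label, obs$score)
#> observation-level AUROC 0.999, AUPRC 0.989 (36 of 541 observations positive)

enc <- summarize_encounter_level(aset)
auroc(enc$label, enc$max_score)
#> encounter-level AUROC 1.000 (3 of 11 encounters deteriorated)

suite <- threshold_suite(obs$label, obs$score)
render_threshold_suite(suite)
#>   measure         medium_risk single high_risk
#> 1 threshold              61.3  50.6      45.6
#> 2 f1_pct                 66.7  95.8      93.5
#> 3 sensitivity_pct        50    94.4     100
#> 4 specificity_pct       100    99.8      99.0
#> 5 ppv_pct               100    97.1      87.8
#> 6 npv_pct                96.6  99.6     100
#> 7 nne                     1     1.03      1.14
```

The fixture's warning signal is deliberately strong, so discrimination is
near-perfect and the NNE is close to 1; on realistic streams the medium-risk
(sensitivity-targeted) threshold typically carries an NNE in the tens —
dozens of alerts reviewed per true positive. The full pipeline (lead-time
grid, calibration, parity audit, JSON/CSV report bundle) runs with:

```r
cfg <- validation_config(simulate = TRUE,
                         sim = sim_config(n_encounters = 500, seed = 1),
                         seed = 1, out_dir = "report")
bundle <- run_full_validation(cfg)
```

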