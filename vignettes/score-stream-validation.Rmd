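---
title: "Validating an inpatient deterioration score stream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating an inpatient deterioration score stream}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detvalid)
```

# The evaluation problem

An inpatient deterioration model emits a probabilistic score in [0, 100] for
every hospitalized adult on a fixed cadence — here taken as every 15
minutes. The composite outcome is *deterioration*: the first of mechanical
ventilation, ICU transfer, or death, with death timestamped at discharge.
`detvalid` evaluates any such score stream retrospectively. It does not
model the score's internals; it answers the questions an implementing
health system must answer: how well does the stream discriminate, how early,
at what alert burden, how well calibrated is it, and does it perform
equitably across demographic subgroups?

# Cohort assembly and its assumptions

`parse_cohort()` validates three tables (encounters, predictions, events)
and `build_analysis_set()` applies the exclusion cascade, in a fixed order:

1. encounters below the minimum age (default 18 years) are removed;
2. predictions in preoperative, intraoperative, ICU, or labor-and-delivery
   locations are removed — surgical care implies planned intubation, ICU
   patients have already deteriorated, and obstetric populations are
   typically outside such models' training data;
3. each encounter's first deterioration event is computed; simultaneous
   events resolve by the priority mechanical ventilation > ICU transfer >
   death, since ventilation is the most specific escalation and
   death-at-discharge timestamps are coarse;
4. encounters in which a comfort-care order precedes the first event are
   removed whole — once care goals change, escalation events no longer
   measure model failure. We implement this as whole-encounter removal
   rather than suppressing only post-order events; the latter reading would
   retain the pre-order stream with an all-negative label and mix two
   different censoring mechanisms in one cohort;
5. predictions at or after the first event are removed, with the boundary
   closed (`ts >= event` is removed): a score concurrent with deterioration
   offers no warning. The convention for a prediction exactly at the event
   instant is genuinely open in practice; we chose the conservative side and
   apply it uniformly;
6. encounters left with no predictions are removed (this also removes
   encounters that deteriorate at or before their first score).

All window arithmetic is done in minutes since admission (timestamps are
parsed as ISO-8601 UTC), which keeps the cascade immune to daylight-saving
ambiguities. Every step writes to an exclusion ledger, and the package
asserts conservation: input predictions = retained + sum of removals.

# Labeling

*Observation level*: each retained score at time `t` is labeled positive
when the qualifying event lies in the half-open window `(t, t + L]` — open
at `t` (the concurrent score was already excluded) and closed at the
horizon. The headline setting is `L = 12` hours; the sweep grid is
{3, 6, 12, 24, 38, 72} hours. For component outcomes the qualifying event is
the first event of that type; scores after the composite first event do not
exist by construction, so component labelings never see post-deterioration
data.

*Encounter level*: one unit per hospitalization, the maximum retained score
(earliest timestamp on ties), labeled by whether deterioration ever
occurred. This is the harder task — a single high excursion anywhere in a
long stay flags the encounter — and encounter-level discrimination is
typically substantially lower than observation-level.

# Metrics and intervals

AUROC uses the rank-sum estimator (ties count one half), equivalent to
exhaustive pair counting and computed in O(n log n). Average precision is
the recall-increment-weighted mean of precision over descending unique
thresholds; for constant scores it equals prevalence exactly. Proportions
(sensitivity, specificity, PPV, NPV) carry Wilson score intervals, which
behave sensibly at extreme counts. Curve metrics and F1 take percentile
bootstrap intervals (default B = 1000, seeded); at the observation level the
bootstrap resamples *encounters*, not observations, because scores within a
stay are strongly autocorrelated and an i.i.d. bootstrap would be
anti-conservative. Replicates that collapse to a single class are skipped
and counted, with a warning past 10%.

Calibration uses 20 equal-width bins on predicted risk, taken as
`score / 100` since the score is itself scaled as a probability in
percent. Bins are right-open except the last (risk 1.0 falls in bin 20);
empty bins are reported with count 0 and an absent observed fraction —
quantile binning was rejected because it hides exactly the sparse high-risk
region that threshold selection cares about.

The positive-classification convention is `score >= threshold` everywhere,
including threshold search.

# Threshold selection

Candidate thresholds are the unique observed scores — no interpolation, so
any reported threshold is attainable on the data. Three rules:

* **medium risk** — the largest threshold with sensitivity at or above the
  target (default 0.50). Sensitivity is non-increasing in the threshold, so
  this is the tightest achiever; with a fine-grained score the attained
  sensitivity sits just above target.
* **single** — the F1-maximizing threshold; exact ties resolve to the lower
  threshold (higher sensitivity), the safer clinical default.
* **high risk** — PPV is not monotone in the threshold, so all candidates
  are enumerated; among those with PPV at or above the target (default
  0.10) the maximal-sensitivity one is chosen. If no candidate achieves the
  target, the argmax-PPV threshold is returned with an `attained = FALSE`
  flag rather than an error, since on real streams a 10% PPV can be near
  the ceiling of what the score can produce.

Each operating point reports NNE = 1/PPV with the interval obtained by
inverting and swapping the PPV interval endpoints.

# Subgroup parity audit

The audit runs at the encounter level. For each protected group (non-White
race categories vs White; Hispanic and chose-not-to-answer vs other
ethnicity; female vs male; under-60 vs 60-and-over, the age cut at 60
years) it reports three ratios: AUROC parity, sensitivity parity (equal
opportunity) and PPV parity, each protected/reference. Sensitivity and PPV
are measured at one threshold — the max-F1 threshold computed on the *full*
cohort, not per group, because deployed thresholds are shared. The combined
measure sums the three parities and reports the deviation
`100 · (sum/3 − 1)`; the raw sum is also emitted so either aggregate
reading is recoverable. Groups with fewer than 20 encounters or 2 events,
a single outcome class, or no flagged encounters are flagged not estimable
with their counts — never silently dropped or returned as NaN. Intersectional
(multi-axis) audits are out of scope: subgroup sparsity makes them
unreliable at realistic cohort sizes.

# The synthetic cohort generator

No real stream ships with the package, so the generator provides ground
truth. Its defaults emulate the cohort this style of validation targets:
scores every 15 minutes; length of stay lognormal with median 3.1 days
(IQR roughly 2–5); encounter-level deterioration prevalence 10.3%; time
from admission to deterioration lognormal with median 68 hours (IQR roughly
39–109); event types split 25/60/15 between ventilation, ICU transfer and
death; demographic mixes typical of a large Midwestern US health system;
2% of encounters carry a comfort-care order and 5% begin in a perioperative
location. Death events land exactly at discharge, and ICU transfers flip
subsequent location labels to `icu`, so every exclusion rule is exercised
on simulated data.

Two modes:

* **binormal** — scores within the 12-hour pre-event window are drawn from
  a truncated normal `N(mu_pos, sigma_pos)`, all others from
  `N(mu_neg, sigma_neg)`. The population observation-level AUROC then has
  the closed form `pnorm((mu_pos − mu_neg) / sqrt(sigma_neg² +
  sigma_pos²))`; the defaults set the separation to exactly one combined
  standard deviation, i.e. AUROC `pnorm(1) ≈ 0.8413`. A warning flags
  configurations where the [0,100] truncation bites (> 1% of class mass).
* **hazard** — a latent per-encounter severity drives an exponential event
  hazard (the baseline is calibrated by quadrature + root finding to the
  prevalence target when unspecified) and a noisy score with a warning
  signal `A · exp(−λ · hours-to-event)`; with decay λ > 0, observation-level
  AUROC falls as the lead time grows, which is what the lead-time sweep
  tests lean on.

Randomness uses R's default generator with per-encounter substreams derived
from the master seed, so encounter *i* is byte-identical whatever the cohort
size, and one seed yields one output.

Bias knobs inject ground-truth inequity: a per-group score shift, an
event-rate multiplier, and a `signal_mask_rate` — the fraction of a group's
event encounters whose stream is drawn from the no-event distribution,
which is a direct multiplicative sensitivity deficit. `inject_subgroup_bias()`
applies shift and rate effects post hoc to already-simulated tables.

What the generator does *not* emulate: within-stay autocorrelation beyond
the event-window structure (binormal scores are conditionally i.i.d.),
repeat hospitalizations of one patient, miscalibration patterns,
comorbidity-outcome correlation, and care-practice differences between
demographic groups. Tests passing on this generator therefore certify the
*evaluation machinery* — labeling, metrics, threshold search, parity
arithmetic — not any claim about real-world model performance.

# Verification design and problem sizes

The test suite checks every metric against an independent oracle written in
its naive form (exhaustive pair counting for AUROC, the literal step sum
for average precision, a brute-force window scan for labels, closed-form
Wilson), across hundreds of randomized instances with ties. Wilson coverage
at n = 100, p = 0.1 is verified by exact binomial enumeration — the
infinite-replicate limit of a Monte-Carlo coverage experiment — against a
95% ± 1.5% band. The binormal recovery experiment uses 800 encounters
(about 3 × 10⁵ retained observations), which puts the Monte-Carlo standard
error of the empirical AUROC near 0.004, comfortably inside the ±0.01
acceptance band, with a 200-replicate encounter-cluster bootstrap covering
the closed form. The parity experiments use 20 000 encounters (about 10⁴
per compared group on the sex and age axes) with a widely separated
binormal configuration (mu_neg = 30, mu_pos = 70, sigma = 8): the audit
measures ratio arithmetic, and a weakly separated score would let
false-alarm contamination of the sensitivity numerator mask an injected
deficit. With the wide separation, a 20% `signal_mask_rate` appears as
sensitivity parity 0.80 to within Monte-Carlo error.

# Limitations

* Labeling is deterministic windowing; there is no competing-risks or
  censoring-time model, matching standard practice for early-warning
  validation but understating uncertainty near discharge.
* AUROC/AUPRC intervals use the percentile bootstrap, not an analytic
  variance; for very large streams the bootstrap dominates run time and
  can be disabled per call.
* The parity audit reports point-estimate ratios; group-specific interval
  estimation (and any correction for multiple subgroup comparisons) is left
  to the caller, as subgroup differences at this scale are exploratory.
* Observed-score threshold enumeration reproduces any threshold actually
  attainable on the data, but cannot emit a threshold between two observed
  scores.
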