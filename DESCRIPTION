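Package: detvalid
Title: Validation and Fairness Auditing of Inpatient Deterioration Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the external validation of continuous inpatient
    deterioration risk scores (probabilistic scores in [0,100] emitted on a
    fixed cadence, e.g. every 15 minutes). Implements cohort exclusion rules
    for score streams (care-location exclusions, comfort-care encounters,
    post-event scores), observation- and encounter-level outcome labeling
    against lead-time windows, discrimination and calibration metrics
    (AUROC, average precision, Wilson score intervals, cluster bootstrap),
    clinically informed threshold selection with alert-burden summaries
    (number needed to evaluate), a subgroup parity audit (AUROC, sensitivity
    and PPV parity with a combined deviation), and a seeded synthetic
    hospital-cohort generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    arrow,
    pROC,
    withr
Config/testthat/edition: 3
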