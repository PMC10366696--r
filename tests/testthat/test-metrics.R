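# Core metrics: worked examples, invariants, and independent-oracle checks.

test_that("auroc matches exhaustive pair counting on worked examples", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auroc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1.0)     # perfect separation
  expect_equal(auroc(c(0, 1, 0, 1), rep(5, 4)), 0.5)          # all tied
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "negative",
               class = "detvalid_metric_error")
  expect_error(auroc(c(0, 0), c(0.2, 0.3)), "positive",
               class = "detvalid_metric_error")
})

test_that("rank-sum auroc equals pair counting on random tied instances", {
  set.seed(902)
  for (r in 1:60) {
    inst <- random_instance(sample(10:200, 1))
    expect_equal(auroc(inst$labels, inst$scores),
                 oracle_auroc_pairs(inst$labels, inst$scores),
                 tolerance = 1e-12)
  }
})

test_that("auroc complement and monotone-transform invariances hold", {
  set.seed(903)
  for (r in 1:20) {
    n <- sample(20:100, 1)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) labels[1:2] <- c(0L, 1L)
    scores <- rnorm(n) # tie-free almost surely
    expect_equal(auroc(labels, scores) + auroc(labels, -scores), 1)
    expect_equal(auroc(labels, scores), auroc(labels, exp(scores / 3)))
  }
})

test_that("average precision matches the brute-force step sum", {
  expect_equal(average_precision(c(1, 0, 1), c(0.9, 0.8, 0.7)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(average_precision(c(1, 1, 0, 0), c(4, 3, 2, 1)), 1.0)
  # constant scores: single threshold, AP equals prevalence
  expect_equal(average_precision(c(1, 0, 0, 0), rep(7, 4)), 0.25)
  set.seed(904)
  for (r in 1:60) {
    inst <- random_instance(sample(10:200, 1))
    expect_equal(average_precision(inst$labels, inst$scores),
                 oracle_average_precision(inst$labels, inst$scores),
                 tolerance = 1e-12)
  }
})

test_that("wilson interval matches the closed form and its boundary cases", {
  w <- wilson_interval(8, 10)
  expect_equal(unname(w), oracle_wilson(8, 10), tolerance = 1e-10)
  expect_equal(round(w[["lower"]], 3), 0.490)
  expect_equal(round(w[["upper"]], 3), 0.943)
  expect_equal(wilson_interval(0, 10)[["lower"]], 0)
  w5 <- wilson_interval(5, 10)
  expect_equal(w5[["lower"]] + w5[["upper"]], 1, tolerance = 1e-12) # symmetric at 0.5
  expect_error(wilson_interval(1, 0), class = "detvalid_validation_error")
})

test_that("operating point counts, proportions and flags are correct", {
  op <- operating_point(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1), 0.7)
  expect_equal(c(op$tp, op$fp, op$fn, op$tn), c(2, 1, 0, 1))
  expect_equal(op$sensitivity[["est"]], 1.0)
  expect_equal(op$ppv[["est"]], 2 / 3)
  expect_equal(op$nne[["est"]], 1.5)
  # threshold above the maximum: nothing flagged, ppv absent (not 0/Inf)
  hi <- operating_point(c(1, 0), c(0.5, 0.4), 0.9)
  expect_false(hi$ppv_defined)
  expect_true(is.na(hi$ppv[["est"]]))
  expect_equal(hi$specificity[["est"]], 1.0)
  # threshold at the minimum score: all flagged under the >= convention
  lo <- operating_point(c(1, 0), c(0.5, 0.4), 0.4)
  expect_equal(lo$sensitivity[["est"]], 1.0)
  expect_equal(lo$specificity[["est"]], 0.0)
})

test_that("operating points are consistent with the emitted curve points", {
  set.seed(905)
  inst <- random_instance(150)
  cp <- curve_points(inst$labels, inst$scores)
  for (i in sample(nrow(cp), min(8, nrow(cp)))) {
    op <- operating_point(inst$labels, inst$scores, cp$threshold[i])
    expect_equal(op$sensitivity[["est"]], cp$sensitivity[i])
    expect_equal(1 - op$specificity[["est"]], cp$fpr[i], tolerance = 1e-12)
    expect_equal(op$ppv[["est"]], cp$precision[i])
  }
})

test_that("f1 and nne identities hold on worked values", {
  expect_equal(round(100 * f1_score(0.108, 0.082), 1), 9.3)
  expect_equal(f1_score(0.3, 0.3), 0.3) # harmonic mean of equal values
  expect_equal(f1_score(0.5, 0), 0)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(round(nne(0.021), 1), 47.6)
  expect_equal(round(nne(0.10), 1), 10.0)
  expect_equal(nne(1), 1)
  expect_warning(expect_true(is.na(nne(0))), "NNE undefined")
  # interval by inverting and swapping the PPV interval endpoints
  v <- nne(0.1, ppv_interval = c(0.08, 0.125))
  expect_equal(unname(attr(v, "interval")), c(8, 12.5))
})

test_that("calibration bins partition [0,1] and flag empty bins", {
  risks <- c(0.02, 0.07, 0.12, 0.55, 1.0)
  tab <- calibration_table(c(0, 0, 1, 1, 1), risks, n_bins = 20)
  expect_equal(nrow(tab), 20)
  expect_equal(sum(tab$n), 5)
  expect_equal(tab$n[tab$bin == 1], 1)   # 0.02
  expect_equal(tab$n[tab$bin == 20], 1)  # risk exactly 1 lands in the last bin
  expect_true(is.na(tab$observed_fraction[tab$bin == 4])) # (0.15, 0.20]: empty
  # all risks in one bin: the other 19 rows kept with zero counts
  one <- calibration_table(c(0, 1), c(0.31, 0.32), n_bins = 20)
  expect_equal(sum(one$n == 0), 19)
})

test_that("calibration recovers Bernoulli(risk) event fractions", {
  set.seed(906)
  risk <- runif(1e5)
  y <- rbinom(1e5, 1, risk)
  tab <- calibration_table(y, risk, n_bins = 20)
  # each bin holds ~5000 draws; observed fraction tracks mean predicted risk
  expect_true(all(abs(tab$observed_fraction - tab$mean_predicted) < 0.03))
})

test_that("bootstrap intervals are seeded, degenerate-safe and cluster-aware", {
  set.seed(907)
  labels <- rbinom(400, 1, 0.3)
  scores <- rnorm(400) + labels
  ci1 <- bootstrap_interval(auroc, labels, scores, B = 200, seed = 5)
  ci2 <- bootstrap_interval(auroc, labels, scores, B = 200, seed = 5)
  expect_identical(unclass(ci1)[1:2], unclass(ci2)[1:2])
  # constant statistic -> zero-width interval
  cst <- bootstrap_interval(function(l, s) 0.42, labels, scores, B = 100, seed = 1)
  expect_equal(unname(cst[1]), unname(cst[2]))
  # single-class resamples are skipped and counted
  tiny_l <- c(1, rep(0, 19))
  tiny_s <- rnorm(20)
  suppressWarnings(
    ci3 <- bootstrap_interval(auroc, tiny_l, tiny_s, B = 100, seed = 2)
  )
  expect_gt(attr(ci3, "n_skipped"), 0)
  # cluster bootstrap keeps clusters intact (statistic sees whole encounters)
  cl <- rep(1:40, each = 10)
  sizes <- integer(0)
  stat <- function(l, s) { sizes <<- c(sizes, length(l)); auroc(l, s) }
  invisible(bootstrap_interval(stat, labels, scores, B = 100, seed = 3, cluster = cl))
  expect_true(all(sizes %% 10 == 0))
})

test_that("auroc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(908)
  inst <- random_instance(300)
  ref <- as.numeric(pROC::auc(pROC::roc(inst$labels, inst$scores,
                                        quiet = TRUE, direction = "<")))
  expect_equal(auroc(inst$labels, inst$scores), ref, tolerance = 1e-10)
})
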