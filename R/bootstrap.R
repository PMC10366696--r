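# Seeded percentile bootstrap, with optional resampling by cluster
# (encounter) so that within-encounter correlation of observations is
# respected when interval-estimating observation-level metrics.

#' Percentile bootstrap interval for a labeled-data statistic
#'
#' Resamples units (or whole clusters when `cluster` is given) with
#' replacement `B` times, evaluates `statistic(labels, scores)` on each
#' replicate, and returns the percentile interval. Replicates on which the
#' statistic errors (e.g. a resample containing a single class) are skipped
#' and counted; more than 10% skips triggers a warning.
#'
#' @param statistic Function of `(labels, scores)` returning a scalar.
#' @param labels,scores Parallel vectors of labeled units.
#' @param B Number of replicates (at least 100).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param level Confidence level (default 0.95).
#' @param cluster Optional vector of cluster keys parallel to `labels`;
#'   when given, clusters are resampled as blocks.
#' @return Named numeric `c(lower, upper)` with attributes `n_skipped` and
#'   `replicates` (the kept replicate values).
#' @export
bootstrap_interval <- function(statistic, labels, scores, B = 1000, seed = NULL,
                               level = 0.95, cluster = NULL) {
  if (B < 100) abort_validation("B must be at least 100")
  if (length(labels) != length(scores)) abort_metric("labels/scores length mismatch")
  if (!is.null(seed)) set.seed(seed)

  n <- length(labels)
  if (!is.null(cluster)) {
    if (length(cluster) != n) abort_metric("cluster key length mismatch")
    idx_by_cluster <- split(seq_len(n), cluster)
    n_cl <- length(idx_by_cluster)
  }

  reps <- numeric(B)
  keep <- logical(B)
  for (b in seq_len(B)) {
    idx <- if (is.null(cluster)) {
      sample.int(n, n, replace = TRUE)
    } else {
      unlist(idx_by_cluster[sample.int(n_cl, n_cl, replace = TRUE)],
             use.names = FALSE)
    }
    val <- tryCatch(statistic(labels[idx], scores[idx]), error = function(e) NA_real_)
    if (!is.na(val)) {
      reps[b] <- val
      keep[b] <- TRUE
    }
  }
  n_skip <- sum(!keep)
  if (n_skip > 0.1 * B) {
    rlang::warn(sprintf("bootstrap skipped %d of %d replicates (degenerate resamples)",
                        n_skip, B))
  }
  vals <- reps[keep]
  if (!length(vals)) abort_metric("all bootstrap replicates degenerate")
  alpha <- (1 - level) / 2
  q <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(c(lower = q[1], upper = q[2]),
            n_skipped = n_skip, replicates = vals)
}
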