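`%||%` <- function(x, y) if (is.null(x)) y else x

abort_schema <- function(msg) rlang::abort(msg, class = "detvalid_schema_error")
abort_validation <- function(msg) rlang::abort(msg, class = "detvalid_validation_error")
abort_metric <- function(msg) rlang::abort(msg, class = "detvalid_metric_error")
abort_config <- function(msg) rlang::abort(msg, class = "detvalid_config_error")

#' Percentage of a count, rounded for display
#'
#' Convenience helper used throughout the descriptive tables: `100 * x / n`
#' rounded to a fixed number of decimals (one, matching the precision at
#' which clinical validation tables are customarily printed).
#'
#' @param x Numerator count.
#' @param n Denominator count.
#' @param digits Decimals to keep (default 1).
#' @return Numeric percentage on the 0-100 scale.
#' @examples
#' pct(1436, 13918) # 10.3
#' @export
pct <- function(x, n, digits = 1) {
  if (any(n <= 0)) abort_validation("`n` must be positive in pct()")
  round(100 * x / n, digits)
}

# Parse timestamps: pass POSIXct through, parse ISO-8601 character, promote Date.
parse_ts <- function(x, what = "timestamp") {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) return(as.POSIXct(x, tz = "UTC"))
  if (is.character(x) || is.factor(x)) {
    out <- readr::parse_datetime(as.character(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad)) {
      abort_validation(sprintf(
        "unparseable %s at row(s) %s (expected ISO-8601)",
        what, paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
    attr(out, "tzone") <- "UTC"
    return(out)
  }
  if (is.numeric(x) && all(is.na(x))) {
    return(as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC"))
  }
  if (is.logical(x) && all(is.na(x))) {
    return(as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC"))
  }
  abort_schema(sprintf("cannot interpret %s column of class <%s>", what, class(x)[1]))
}

# Minutes elapsed from `from` to `to` (numeric, may be fractional).
minutes_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "mins"))
}

check_binary_labels <- function(labels) {
  if (!length(labels)) abort_metric("empty label vector")
  u <- unique(labels[!is.na(labels)])
  if (!all(u %in% c(0, 1, TRUE, FALSE))) {
    abort_metric("labels must be binary (0/1 or logical)")
  }
  as.integer(labels)
}

# Substream seed for encounter i under master seed s; stays inside 32-bit range.
substream_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(i) * 16807
  as.integer(s %% 2147483587) + 1L
}
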