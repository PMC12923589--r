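#' Empirical quantile with the package-wide convention
#'
#' All quantile thresholds in the package (MSEA score thresholds, hub-degree
#' cutoffs) use the inverse empirical CDF with averaging at discontinuities
#' (`stats::quantile()` type 2), so thresholds are reproducible across
#' implementations and do not interpolate between observed values except at
#' exact jump points.
#'
#' @param x Numeric vector of observations.
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, one per probability.
#' @export
#' @examples
#' empirical_quantile(1:20, c(0.5, 0.75)) # 10.5, 15.5
empirical_quantile <- function(x, probs) {
  stopifnot(is.numeric(x), length(x) > 0, all(probs >= 0 & probs <= 1))
  unname(stats::quantile(x, probs = probs, type = 2, names = FALSE))
}

# shared column checker: abort naming the missing columns
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s (has: %s)",
      what, paste(missing, collapse = ", "), paste(names(df), collapse = ", ")
    ))
  }
  invisible(df)
}

# coerce a data frame (or marker-table-like object) to a validated marker table
as_marker_table <- function(x, what = "markers") {
  if (inherits(x, "clumped_markers")) x <- x$markers
  check_columns(x, c("marker_id", "score"), what)
  if (anyDuplicated(x$marker_id) > 0) {
    abort(sprintf("%s: duplicate marker_id values are not allowed", what))
  }
  if (any(!is.finite(x$score)) || any(x$score < 0)) {
    abort(sprintf("%s: scores must be finite and non-negative", what))
  }
  as_tibble(x)
}

# deterministic child seeds for per-unit parallel-safe reproducibility;
# kept well below 2^31
derive_seed <- function(master, index) {
  (as.integer(master) %% 1000003L) * 1009L + as.integer(index)
}
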