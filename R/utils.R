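# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Deterministic decimal rounding where halves go away from zero (67.5 -> 68),
#' unlike base [round()]'s banker's rounding. All printed percentages and
#' clinical means in this package use this rule so that results match tabular
#' reporting conventions.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(67.5 / 1)      # 68
#' round_half_up(4.25, 1)       # 4.3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # epsilon guards against representation error (e.g. 67.5 stored as 67.4999...)
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# check that `df` has the named columns, error naming the missing ones
require_columns <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L)
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}

# deterministic row ordering for report tables: case, sample, gene, then the rest
order_report_rows <- function(df) {
  pref <- intersect(c("case_id", "sample_id", "gene", "basis", "stratum",
                      "timepoint", "status", "region", "category"),
                    names(df))
  keys <- c(pref, setdiff(names(df), pref))
  keys <- keys[vapply(df[keys], function(x) is.atomic(x), logical(1))]
  if (length(keys) == 0L || nrow(df) < 2L) return(df)
  df[do.call(order, lapply(df[keys], as.character)), , drop = FALSE]
}
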