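# Internal helpers shared across modules. Coordinates are 1-based inclusive
# throughout (IRanges convention); interval length is end - start + 1.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Length of a 1-based inclusive interval
#' @noRd
iv_len <- function(start, end) pmax(0, end - start + 1)

#' Overlap length of two 1-based inclusive intervals (0 when disjoint)
#' @noRd
iv_overlap <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Check that a data frame has the given columns
#' @noRd
need_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stopf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  }
  invisible(df)
}

empty_df <- function(proto) proto[0L, , drop = FALSE]

#' Deterministic seed derivation for per-sample streams, kept below 2^31
#' @noRd
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483587) + 1L
}
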