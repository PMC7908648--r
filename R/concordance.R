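# Call-set concordance: TP/FP/FN bookkeeping between a query and a truth
# set under breakpoint-tolerance / reciprocal-overlap matching, with
# optional multipart matching, and sensitivity stratified by variant size.

#' Default concordance matching criteria
#'
#' Breakpoints within 1000 bases, or reciprocal overlap of at least 80% of
#' the variant length, allowing multiple matching HIGH/PASS parts to
#' jointly cover one truth variant. Microarray-style comparison uses
#' `concordance_criteria(breakpoint_tol = NA, reciprocal = 0.5)`.
#'
#' @param breakpoint_tol Breakpoint tolerance in bases (`NA` disables the
#'   clause).
#' @param reciprocal Reciprocal-overlap threshold.
#' @param allow_multipart Allow several query parts to jointly match one
#'   truth variant (all parts must be HIGH or PASS).
#' @return List of criteria.
#' @export
concordance_criteria <- function(breakpoint_tol = 1000, reciprocal = 0.8,
                                 allow_multipart = TRUE) {
  list(breakpoint_tol = breakpoint_tol, reciprocal = reciprocal,
       allow_multipart = allow_multipart)
}

#' Does a single query call match a truth call?
#' @noRd
single_match <- function(q, t, crit) {
  if (q$chrom != t$chrom || q$svtype != t$svtype) return(FALSE)
  if (!is.na(crit$breakpoint_tol) &&
      abs(q$start - t$start) <= crit$breakpoint_tol &&
      abs(q$end - t$end) <= crit$breakpoint_tol) return(TRUE)
  ov <- iv_overlap(q$start, q$end, t$start, t$end)
  ql <- q$end - q$start + 1; tl <- t$end - t$start + 1
  ov / ql >= crit$reciprocal && ov / tl >= crit$reciprocal
}

#' Compare a query call set against a truth set
#'
#' Each truth variant is a true positive when matched by at least one
#' query variant (breakpoints within tolerance or reciprocal overlap), or
#' — in multipart mode — by several HIGH/PASS query parts whose union
#' satisfies the reciprocal-overlap criterion against it; otherwise it is
#' a false negative. Query variants matching no truth variant are false
#' positives. Sensitivity is TP / (TP + FN).
#'
#' @param query,truth Data frames with `chrom`, `start`, `end`, `svtype`
#'   (query may carry `tranche` for multipart eligibility).
#' @param criteria See [concordance_criteria()].
#' @return List of class `concordance_result`: `tp`, `fp`, `fn`,
#'   `sensitivity`, `truth_matched` (logical vector), `query_matched`
#'   (logical vector), `assignments` (data frame truth_idx/query_idx).
#' @export
match_callsets <- function(query, truth, criteria = concordance_criteria()) {
  nq <- nrow(query); nt <- nrow(truth)
  truth_matched <- logical(nt)
  query_matched <- logical(nq)
  assignments <- list()
  bad_types <- setdiff(unique(query$svtype), unique(truth$svtype))
  if (nt && length(bad_types)) {
    warnf("query type(s) absent from truth set: %s",
          paste(bad_types, collapse = ", "))
  }
  for (i in seq_len(nt)) {
    t <- truth[i, ]
    hit <- which(vapply(seq_len(nq), function(j) {
      single_match(query[j, ], t, criteria)
    }, logical(1)))
    if (length(hit)) {
      truth_matched[i] <- TRUE
      query_matched[hit] <- TRUE
      assignments[[length(assignments) + 1L]] <-
        data.frame(truth_idx = i, query_idx = hit)
      next
    }
    if (isTRUE(criteria$allow_multipart)) {
      eligible <- query$chrom == t$chrom & query$svtype == t$svtype
      if (!is.null(query$tranche)) {
        eligible <- eligible & query$tranche %in% c("HIGH", "PASS")
      }
      parts <- which(eligible &
                       iv_overlap(query$start, query$end, t$start, t$end) > 0)
      if (length(parts) >= 2) {
        covered <- sum(IRanges::width(IRanges::intersect(
          IRanges::reduce(IRanges::IRanges(query$start[parts], query$end[parts])),
          IRanges::IRanges(t$start, t$end))))
        union_len <- sum(IRanges::width(IRanges::reduce(
          IRanges::IRanges(query$start[parts], query$end[parts]))))
        tl <- t$end - t$start + 1
        if (covered / tl >= criteria$reciprocal &&
            covered / union_len >= criteria$reciprocal) {
          truth_matched[i] <- TRUE
          query_matched[parts] <- TRUE
          assignments[[length(assignments) + 1L]] <-
            data.frame(truth_idx = i, query_idx = parts)
        }
      }
    }
  }
  tp <- sum(truth_matched); fn <- nt - tp; fp <- sum(!query_matched)
  structure(list(
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    truth_matched = truth_matched, query_matched = query_matched,
    assignments = if (length(assignments)) do.call(rbind, assignments) else
      data.frame(truth_idx = integer(), query_idx = integer())
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance: TP %d, FP %d, FN %d, sensitivity %s\n",
              x$tp, x$fp, x$fn,
              ifelse(is.na(x$sensitivity), "n/a",
                     sprintf("%.3f", x$sensitivity))))
  invisible(x)
}

#' Default size bins for stratified sensitivity
#' @export
DEFAULT_SIZE_BINS <- c(0, 500, 1e3, 5e3, 1e4, 5e4, 1e5, 5e5, 5e6)

#' Sensitivity stratified by truth-variant size
#'
#' @param result A [match_callsets()] result.
#' @param truth The truth data frame the result was computed against.
#' @param bins Numeric vector of bin edges (default 0-500, 500-1k, 1k-5k,
#'   5k-10k, 10k-50k, 50k-100k, 100k-500k, 500k-5M).
#' @return Data frame `bin`, `n`, `tp`, `sensitivity` (`NA` for empty
#'   bins).
#' @export
sensitivity_by_size <- function(result, truth, bins = DEFAULT_SIZE_BINS) {
  len <- truth$end - truth$start + 1
  bin <- cut(len, breaks = bins, include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    idx <- which(bin == b)
    tp <- sum(result$truth_matched[idx])
    data.frame(bin = b, n = length(idx), tp = tp,
               sensitivity = if (length(idx)) tp / length(idx) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
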