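# Confidence tranches and per-variant quality attributes: mapping quality,
# GC content, sequence compression ratio, segmental-duplication matching.

#' Assign a High/Pass/Low confidence tranche
#'
#' For CNVs (depth-supported calls): HIGH when larger than 100 kb, or
#' larger than 10 kb with confidently mapped reads (average mapping quality
#' across the variant > 55); PASS when larger than 10 kb, or at most 10 kb
#' with at least two supporting split reads or discordant pairs. For
#' copy-number-neutral SVs: HIGH with at least 10 supporting reads and at
#' least one from each source (SR and DP); PASS with at least 6 supporting
#' reads. Everything else is LOW.
#'
#' @param length Variant length in bases.
#' @param cnv Logical, depth-supported CNV state (see [flag_cnv()]).
#' @param su,sr,dp Supporting read counts (su = sr + dp).
#' @param avg_mq Average mapping quality across the variant.
#' @param rules Threshold list; the defaults implement the standard
#'   tranche definitions and may be recalibrated.
#' @return Character scalar: "HIGH", "PASS" or "LOW".
#' @export
classify_confidence <- function(length, cnv, su, sr = NA_integer_,
                                dp = NA_integer_, avg_mq = NA_real_,
                                rules = tranche_rules()) {
  if (isTRUE(cnv)) {
    if (length > rules$cnv_high_len) return("HIGH")
    if (length > rules$cnv_mq_len && is.finite(avg_mq) &&
        avg_mq > rules$cnv_high_mq) return("HIGH")
    if (length > rules$cnv_mq_len) return("PASS")
    if (su >= rules$cnv_pass_su) return("PASS")
    return("LOW")
  }
  sr <- if (is.na(sr)) 0L else sr
  dp <- if (is.na(dp)) 0L else dp
  if (su >= rules$sv_high_su && sr >= 1 && dp >= 1) return("HIGH")
  if (su >= rules$sv_pass_su) return("PASS")
  "LOW"
}

#' @rdname classify_confidence
#' @export
tranche_rules <- function() {
  list(cnv_high_len = 100000, cnv_mq_len = 10000, cnv_high_mq = 55,
       cnv_pass_su = 2, sv_high_su = 10, sv_pass_su = 6)
}

#' GC content of a sequence or variant interval
#'
#' Percentage of G+C among unambiguous bases (A, C, G, T); ambiguous bases
#' are excluded from the denominator. `NA` (flagged) when no unambiguous
#' base exists, e.g. an all-N interval.
#'
#' @param seq A character string or [Biostrings::DNAString] (or a
#'   `DNAStringSet` of reference contigs together with `chrom`, `start`,
#'   `end` to extract the interval).
#' @param chrom,start,end Optional interval when `seq` is a reference set.
#' @return Numeric percentage in \[0, 100\] or `NA`.
#' @export
compute_gc <- function(seq, chrom = NULL, start = NULL, end = NULL) {
  if (methods::is(seq, "DNAStringSet")) {
    stopifnot(!is.null(chrom))
    seq <- Biostrings::subseq(seq[[chrom]], start, end)
  }
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  f <- Biostrings::letterFrequency(seq, c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0) return(NA_real_)
  100 * (f[["C"]] + f[["G"]]) / tot
}

#' Sequence compression ratio
#'
#' The length in bytes of the losslessly compressed sequence divided by the
#' sequence length. The compressor is pinned to DEFLATE (gzip container,
#' default level) so the ratio is reproducible across runs. Tandem-repeat
#' rich sequence compresses well and yields a low ratio; complex sequence a
#' higher one.
#'
#' @param seq Character string (length >= 50 bases).
#' @return Numeric ratio > 0.
#' @export
compute_compression_ratio <- function(seq) {
  if (methods::is(seq, "DNAString")) seq <- as.character(seq)
  if (nchar(seq) < 50) stopf("compression ratio needs >= 50 bases, got %d", nchar(seq))
  length(memCompress(charToRaw(seq), type = "gzip")) / nchar(seq)
}

#' Best-matching segmental duplication for a variant
#'
#' Among segmental-duplication records overlapping the variant, returns
#' the one with the highest sum of overlap length (in % of the variant
#' length) and sequence similarity (in %); `NULL` when none overlaps.
#'
#' @param chrom,start,end Variant interval.
#' @param segdups Data frame with columns `chrom`, `start`, `end`,
#'   `similarity` (percent).
#' @return One-row data frame with added `overlap_pct` and `score`, or
#'   `NULL`.
#' @export
best_segdup_match <- function(chrom, start, end, segdups) {
  if (is.null(segdups) || nrow(segdups) == 0) return(NULL)
  sd <- segdups[segdups$chrom == chrom, , drop = FALSE]
  if (nrow(sd) == 0) return(NULL)
  ov <- iv_overlap(sd$start, sd$end, start, end)
  sd <- sd[ov > 0, , drop = FALSE]
  ov <- ov[ov > 0]
  if (nrow(sd) == 0) return(NULL)
  sd$overlap_pct <- 100 * ov / (end - start + 1)
  sd$score <- sd$overlap_pct + sd$similarity
  best <- sd[which.max(sd$score), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Average mapping quality around breakpoints
#'
#' Mean of the MQ track over windows of +/- `window` bases centered on the
#' two breakpoints.
#'
#' @param track Coverage track (carries the MQ layer).
#' @param chrom,start,end Variant interval.
#' @param window Half-window in bases (default 500).
#' @return Numeric average MQ.
#' @export
breakpoint_avg_mq <- function(track, chrom, start, end, window = 500) {
  a <- region_doc(track, chrom, start - window, start + window)
  b <- region_doc(track, chrom, end - window, end + window)
  mean(c(a$mq, b$mq), na.rm = TRUE)
}
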