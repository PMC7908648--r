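# Evidence extraction: discordant read pairs (DP), split reads (SR),
# insert-size cutoffs and high-coverage excluded regions.
#
# Evidence records are plain data frames so they can be loaded from
# pre-extracted tab-separated tables as well as built from alignment-record
# tables; both paths produce the same schema.

DP_COLS <- c("chrom", "start", "end", "mate_chrom", "orientation", "mapq", "sample_id")
SR_COLS <- c("chrom", "start", "end", "mate_chrom", "orientation", "mapq", "sample_id")

#' Default decoy contigs whose reads are discarded during SR extraction
#' @export
DEFAULT_DECOY_CONTIGS <- c("NC_007605", "hs37d5")

#' Estimate discordant mapping-distance cutoffs from an insert-size sample
#'
#' The mapping distances of normally oriented read pairs in a sample region
#' are sorted; iterating in descending order and accumulating the pair count,
#' the upper cutoff is the distance at which the cumulative count reaches an
#' average of 100 read pairs per Mb of the sampled region. The lower cutoff
#' is obtained symmetrically in ascending order. Ties resolve toward the
#' wider (more permissive) cutoff because the threshold count indexes the
#' sorted vector directly.
#'
#' @param pair_distances Integer/numeric vector of mapping distances of
#'   normally oriented (FR, intra-chromosomal) read pairs.
#' @param region_length Length in bases of the region the pairs were sampled
#'   from (default 4 Mb, matching the default sampling region
#'   contig1:1,000,001-5,000,000).
#' @param pairs_per_mb Threshold density of pairs (default 100 per Mb).
#' @return A list of class `insert_cutoffs` with elements `lower`, `upper`,
#'   `region_length`.
#' @export
compute_insert_cutoffs <- function(pair_distances, region_length = 4e6,
                                   pairs_per_mb = 100) {
  n <- length(pair_distances)
  if (n < 1000) {
    stopf("insert-size estimation needs >= 1000 pair distances, got %d", n)
  }
  if (region_length <= 0) stopf("region_length must be positive")
  k <- max(1L, as.integer(round(pairs_per_mb * region_length / 1e6)))
  if (k > n) {
    stopf("threshold pair count %d exceeds available pairs (%d)", k, n)
  }
  srt <- sort(as.numeric(pair_distances))
  res <- list(lower = srt[k], upper = srt[n - k + 1L],
              region_length = region_length)
  if (res$lower > res$upper) {
    # pathological density: fall back to the full observed range
    res$lower <- srt[1L]
    res$upper <- srt[n]
  }
  class(res) <- "insert_cutoffs"
  res
}

#' @export
print.insert_cutoffs <- function(x, ...) {
  cat(sprintf("insert cutoffs: lower=%g upper=%g (region %g Mb)\n",
              x$lower, x$upper, x$region_length / 1e6))
  invisible(x)
}

#' Extract discordant read pairs from a read-pair table
#'
#' Keeps pairs that are inter-chromosomal, aberrantly oriented (anything but
#' FR), or whose outer mapping distance falls outside the estimated insert
#' cutoffs. Duplicate-marked pairs and pairs falling in excluded regions are
#' dropped, as are pairs below an optional mapping-quality floor.
#'
#' @param pairs Data frame of read-pair records with columns `chrom`,
#'   `start`, `end` (outer span, 1-based inclusive), `mate_chrom`,
#'   `orientation` (one of FR, RF, FF, RR), `mapq`, `sample_id` and
#'   optionally `duplicate` (logical).
#' @param cutoffs An `insert_cutoffs` object.
#' @param exclude Optional excluded-region data frame (`chrom`,`start`,`end`).
#' @param mq_floor Minimum mapping quality (default 0, i.e. no filter).
#' @return Data frame of discordant-pair records (same schema, minus
#'   `duplicate`).
#' @export
extract_discordant_pairs <- function(pairs, cutoffs, exclude = NULL,
                                     mq_floor = 0) {
  need_cols(pairs, DP_COLS, "read-pair table")
  if (!inherits(cutoffs, "insert_cutoffs")) stopf("cutoffs must be insert_cutoffs")
  if (nrow(pairs) == 0) return(pairs[, DP_COLS])
  assert_sorted(pairs, "read-pair table")
  if (!is.null(pairs$duplicate)) pairs <- pairs[!pairs$duplicate, , drop = FALSE]
  inter <- pairs$chrom != pairs$mate_chrom
  dist <- ifelse(inter, NA_real_, pairs$end - pairs$start + 1)
  misoriented <- pairs$orientation != "FR"
  aberrant_dist <- !inter & (dist < cutoffs$lower | dist > cutoffs$upper)
  keep <- (inter | misoriented | aberrant_dist) & pairs$mapq >= mq_floor
  out <- pairs[keep, DP_COLS, drop = FALSE]
  if (!is.null(exclude) && nrow(exclude) && nrow(out)) {
    out <- out[!in_regions(out$chrom, out$start, out$end, exclude), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Extract split reads from a split-alignment table
#'
#' Applies the standard filters: reads on decoy contigs are discarded, as
#' are reads with more than one clipped part, reads whose primary and
#' clipped alignment intervals overlap on the same contig, and reads whose
#' clipped part has more than one supplementary alignment. Surviving reads
#' are normalized to junction records: `start`/`end` are the two
#' breakpoint-proximal coordinates (primary-side first for
#' inter-chromosomal records).
#'
#' @param reads Data frame with columns `primary_chrom`, `primary_start`,
#'   `primary_end`, `clipped_chrom`, `clipped_start`, `clipped_end`,
#'   `clip_side` ("5p" or "3p"), `n_clip_parts`, `n_supp`, `orientation`,
#'   `mapq`, `sample_id`.
#' @param decoy_contigs Contigs to discard (default NC_007605 and hs37d5).
#' @return Data frame of split-read records with columns `chrom`, `start`,
#'   `end`, `mate_chrom`, `orientation`, `mapq`, `sample_id`. A `filter_counts`
#'   attribute logs how many reads each filter removed.
#' @export
extract_split_reads <- function(reads, decoy_contigs = DEFAULT_DECOY_CONTIGS) {
  need_cols(reads, c("primary_chrom", "primary_start", "primary_end",
                     "clipped_chrom", "clipped_start", "clipped_end",
                     "clip_side", "n_clip_parts", "n_supp",
                     "orientation", "mapq", "sample_id"), "split-read table")
  n0 <- nrow(reads)
  decoy <- reads$primary_chrom %in% decoy_contigs |
    reads$clipped_chrom %in% decoy_contigs
  multi_clip <- reads$n_clip_parts > 1
  same_contig <- reads$primary_chrom == reads$clipped_chrom
  overl <- same_contig &
    iv_overlap(reads$primary_start, reads$primary_end,
               reads$clipped_start, reads$clipped_end) > 0
  multi_supp <- reads$n_supp > 1
  keep <- !(decoy | multi_clip | overl | multi_supp)
  kept <- reads[keep, , drop = FALSE]
  # junction coordinates: the clipped edge of the primary alignment and the
  # matching edge of the clipped alignment
  bp_primary <- ifelse(kept$clip_side == "3p", kept$primary_end, kept$primary_start)
  bp_clipped <- ifelse(kept$clip_side == "3p", kept$clipped_start, kept$clipped_end)
  same <- kept$primary_chrom == kept$clipped_chrom
  out <- data.frame(
    chrom = kept$primary_chrom,
    start = ifelse(same, pmin(bp_primary, bp_clipped), bp_primary),
    end = ifelse(same, pmax(bp_primary, bp_clipped), bp_clipped),
    mate_chrom = kept$clipped_chrom,
    orientation = kept$orientation,
    mapq = kept$mapq,
    sample_id = kept$sample_id,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(
    input = n0, decoy = sum(decoy), multi_clip = sum(multi_clip),
    overlapping_parts = sum(overl), multi_supplementary = sum(multi_supp),
    kept = nrow(out)
  )
  out
}

#' Build excluded regions from a coverage track
#'
#' Returns the maximal intervals whose depth exceeds the threshold
#' (default 300x), at bin resolution.
#'
#' @param track A [coverage_track()] object.
#' @param max_depth Depth threshold (exclusive; default 300).
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
build_excluded_regions <- function(track, max_depth = 300) {
  stopifnot(inherits(track, "coverage_track"))
  out <- lapply(names(track$contigs), function(ctg) {
    depth <- track$contigs[[ctg]]$depth
    hot <- depth > max_depth
    if (!any(hot)) return(NULL)
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    idx <- which(r$values)
    data.frame(
      chrom = ctg,
      start = (starts[idx] - 1L) * track$bin_size + 1L,
      end = pmin(ends[idx] * track$bin_size, track$contigs[[ctg]]$length),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' TRUE for records whose interval overlaps any region in `regions`
#' @noRd
in_regions <- function(chrom, start, end, regions) {
  if (nrow(regions) == 0) return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start, regions$end))
  IRanges::overlapsAny(q, s)
}

assert_sorted <- function(df, what) {
  # sorted within chromosome blocks
  by_chrom <- split(df$start, df$chrom)
  if (any(vapply(by_chrom, is.unsorted, logical(1)))) {
    stopf("%s must be coordinate-sorted", what)
  }
  invisible(TRUE)
}

#' Read or write evidence tables
#'
#' DP/SR evidence round-trips through plain tab-separated tables with a
#' header line, the on-disk evidence format.
#'
#' @param x Evidence data frame.
#' @param path File path.
#' @return `read_evidence_table` returns the data frame; the writer returns
#'   `path` invisibly.
#' @export
write_evidence_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evidence_table
#' @export
read_evidence_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
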