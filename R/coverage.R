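# Depth-of-coverage machinery: binned coverage/mapping-quality tracks,
# genome baseline estimation, per-variant DOC metrics (DRA/DRF), the CNV
# flag, read-depth genotypes and the population coverage SD track.

#' Binned coverage and mapping-quality track
#'
#' A light container holding, per contig, depth and average mapping quality
#' in fixed-width bins tiling the contig without gaps.
#'
#' @param depth Named list of numeric depth vectors, one per contig.
#' @param mq Named list of numeric MQ vectors (same shape as `depth`);
#'   may be `NULL`, in which case MQ 60 is assumed everywhere.
#' @param bin_size Bin width in bases.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(depth, mq = NULL, bin_size = 100L,
                           contig_lengths = NULL) {
  stopifnot(is.list(depth), !is.null(names(depth)))
  if (is.null(mq)) mq <- lapply(depth, function(d) rep(60, length(d)))
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(depth, function(d) length(d) * bin_size, numeric(1))
  }
  contigs <- lapply(names(depth), function(ctg) {
    d <- depth[[ctg]]
    q <- mq[[ctg]]
    if (length(d) != length(q)) stopf("depth/MQ length mismatch on %s", ctg)
    if (any(d < 0)) stopf("negative depth on %s", ctg)
    list(depth = as.numeric(d), mq = as.numeric(q),
         length = as.numeric(contig_lengths[[ctg]]))
  })
  names(contigs) <- names(depth)
  structure(list(contigs = contigs, bin_size = as.integer(bin_size)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d contig(s), bin %d bp\n",
              length(x$contigs), x$bin_size))
  for (ctg in names(x$contigs)) {
    cat(sprintf("  %s: %g bp, mean depth %.1f\n", ctg,
                x$contigs[[ctg]]$length, mean(x$contigs[[ctg]]$depth)))
  }
  invisible(x)
}

#' Per-bin overlap weights of an interval with a binned track
#' @noRd
bin_weights <- function(track, chrom, start, end) {
  ct <- track$contigs[[chrom]]
  if (is.null(ct)) stopf("contig %s not in track", chrom)
  bs <- track$bin_size
  start <- max(1, start); end <- min(ct$length, end)
  if (end < start) return(NULL)
  b1 <- (start - 1) %/% bs + 1
  b2 <- (end - 1) %/% bs + 1
  bins <- b1:b2
  bstart <- (bins - 1) * bs + 1
  bend <- pmin(bins * bs, ct$length)
  w <- iv_overlap(bstart, bend, start, end)
  list(bins = bins, w = w, depth = ct$depth[bins], mq = ct$mq[bins])
}

#' Mean depth and MQ over an interval (overlap-weighted across bins)
#' @noRd
region_doc <- function(track, chrom, start, end, mq_min = NULL) {
  bw <- bin_weights(track, chrom, start, end)
  if (is.null(bw) || sum(bw$w) == 0) return(list(doc = NA_real_, mq = NA_real_, frac_used = 0))
  use <- if (is.null(mq_min)) rep(TRUE, length(bw$bins)) else bw$mq >= mq_min
  frac <- sum(bw$w[use]) / sum(bw$w)
  if (!any(use)) return(list(doc = NA_real_, mq = NA_real_, frac_used = 0))
  list(doc = sum(bw$depth[use] * bw$w[use]) / sum(bw$w[use]),
       mq = sum(bw$mq[use] * bw$w[use]) / sum(bw$w[use]),
       frac_used = frac)
}

#' Estimate baseline genome coverage
#'
#' The autosomal baseline is the median across autosomes of the mean depth
#' in a fixed window per autosome (defaults to positions
#' 20,000,001-30,000,000, clipped to the contig; short toy contigs fall back
#' to the whole contig). X coverage is estimated from the entire X
#' chromosome and Y from its two large unique regions; both are expressed
#' as ratios to the autosomal baseline rounded to the nearest 0.5.
#'
#' @param track A [coverage_track()].
#' @param contig_table Data frame with columns `contig`, `length`, `class`
#'   (one of "autosome", "X", "Y").
#' @param autosome_window Length-2 vector, the per-autosome sampling window.
#' @param y_regions Two-column matrix of unique-region intervals on Y.
#' @return List of class `genome_coverage` with `autosomal`, and per
#'   sex chromosome the raw depth and `ratio` (rounded in steps of 0.5).
#' @export
estimate_genome_coverage <- function(track, contig_table,
                                     autosome_window = c(20000001, 30000000),
                                     y_regions = rbind(c(6641419, 10079253),
                                                       c(13800704, 23668908))) {
  need_cols(contig_table, c("contig", "length", "class"), "contig table")
  autos <- contig_table[contig_table$class == "autosome", , drop = FALSE]
  autos <- autos[autos$contig %in% names(track$contigs), , drop = FALSE]
  if (nrow(autos) == 0) stopf("no autosomes present in coverage track")
  means <- vapply(seq_len(nrow(autos)), function(i) {
    ctg <- autos$contig[i]; len <- autos$length[i]
    s <- autosome_window[1]; e <- autosome_window[2]
    if (s > len) { s <- 1; e <- len } else e <- min(e, len)
    region_doc(track, ctg, s, e)$doc
  }, numeric(1))
  autosomal <- stats::median(means)
  if (!is.finite(autosomal) || autosomal <= 0) {
    stopf("autosomal baseline estimation failed (median %g)", autosomal)
  }
  res <- list(autosomal = autosomal, window_means = stats::setNames(means, autos$contig))
  round_half <- function(x) round(x * 2) / 2
  xc <- contig_table[contig_table$class == "X", , drop = FALSE]
  if (nrow(xc) && xc$contig[1] %in% names(track$contigs)) {
    d <- region_doc(track, xc$contig[1], 1, xc$length[1])$doc
    res$x <- list(contig = xc$contig[1], depth = d,
                  ratio = round_half(d / autosomal))
  }
  yc <- contig_table[contig_table$class == "Y", , drop = FALSE]
  if (nrow(yc) && yc$contig[1] %in% names(track$contigs)) {
    len <- yc$length[1]
    regs <- y_regions
    regs <- regs[regs[, 1] <= len, , drop = FALSE]
    if (nrow(regs) == 0) regs <- rbind(c(1, len))
    regs[, 2] <- pmin(regs[, 2], len)
    docs <- apply(regs, 1, function(r) region_doc(track, yc$contig[1], r[1], r[2])$doc)
    ws <- apply(regs, 1, function(r) r[2] - r[1] + 1)
    d <- sum(docs * ws) / sum(ws)
    res$y <- list(contig = yc$contig[1], depth = d,
                  ratio = round_half(d / autosomal))
  }
  res$contig_class <- stats::setNames(contig_table$class, contig_table$contig)
  class(res) <- "genome_coverage"
  res
}

#' Chromosome-appropriate expected baseline depth for DRA
#' @noRd
baseline_for <- function(genome_est, chrom) {
  cls <- genome_est$contig_class[[chrom]] %||% "autosome"
  if (cls == "X" && !is.null(genome_est$x) && genome_est$x$ratio > 0) {
    return(genome_est$autosomal * genome_est$x$ratio)
  }
  if (cls == "Y" && !is.null(genome_est$y) && genome_est$y$ratio > 0) {
    return(genome_est$autosomal * genome_est$y$ratio)
  }
  genome_est$autosomal
}

#' Chromosomal ploidy implied by the rounded sex-chromosome ratios
#' @noRd
ploidy_for <- function(genome_est, chrom) {
  cls <- genome_est$contig_class[[chrom]] %||% "autosome"
  if (cls == "X" && !is.null(genome_est$x)) return(max(1, round(genome_est$x$ratio * 2)))
  if (cls == "Y" && !is.null(genome_est$y)) return(max(1, round(genome_est$y$ratio * 2)))
  2
}

#' Depth-of-coverage metrics for a variant interval
#'
#' DOC is the mean depth across the interval restricted to bins with
#' average mapping quality >= `mq_min`; if less than one third of the
#' variant length qualifies, the restriction is dropped (`mq_restricted`
#' is then `FALSE`). DRA is DOC over the chromosome-appropriate genome
#' baseline; DRF is DOC over the mean of the two flanking regions of the
#' same length as the variant (a single flank is used at contig edges; DRF
#' is `NA` when neither flank exists).
#'
#' @param chrom,start,end Variant interval (1-based inclusive).
#' @param track Coverage track.
#' @param genome_est A [estimate_genome_coverage()] result.
#' @param mq_min Mapping-quality threshold (default 50).
#' @return List of class `doc_metrics`: `doc`, `dra`, `drf`, `avg_mq`,
#'   `mq_restricted`.
#' @export
compute_doc_metrics <- function(chrom, start, end, track, genome_est,
                                mq_min = 50) {
  stopifnot(end >= start)
  r <- region_doc(track, chrom, start, end, mq_min = mq_min)
  mq_restricted <- TRUE
  if (r$frac_used < 1 / 3) {
    r <- region_doc(track, chrom, start, end, mq_min = NULL)
    mq_restricted <- FALSE
  }
  base <- baseline_for(genome_est, chrom)
  if (!is.finite(base) || base <= 0) stopf("zero baseline coverage for %s", chrom)
  len <- end - start + 1
  ctg_len <- track$contigs[[chrom]]$length
  flank_doc <- function(s, e) {
    if (e < 1 || s > ctg_len || e < s) return(NA_real_)
    rr <- region_doc(track, chrom, max(1, s), min(ctg_len, e),
                     mq_min = if (mq_restricted) mq_min else NULL)
    if (mq_restricted && rr$frac_used < 1 / 3) {
      rr <- region_doc(track, chrom, max(1, s), min(ctg_len, e), mq_min = NULL)
    }
    rr$doc
  }
  lf <- flank_doc(start - len, start - 1)
  rf <- flank_doc(end + 1, end + len)
  fl <- mean(c(lf, rf), na.rm = TRUE)
  drf <- if (is.finite(fl) && fl > 0) r$doc / fl else NA_real_
  structure(list(doc = r$doc, dra = r$doc / base, drf = drf,
                 avg_mq = r$mq, mq_restricted = mq_restricted),
            class = "doc_metrics")
}

#' Flag a variant as a copy-number variant from its DOC ratios
#'
#' A call is a CNV when DRA or DRF departs from the copy-neutral band,
#' i.e. is < 0.8 or > 1.2. An undefined DRF falls back to DRA alone.
#'
#' @param dra,drf Depth ratios (DRF may be `NA`). A `doc_metrics` object may
#'   be given as `dra`.
#' @return Logical.
#' @export
flag_cnv <- function(dra, drf = NA_real_) {
  if (inherits(dra, "doc_metrics")) { drf <- dra$drf; dra <- dra$dra }
  if (!is.finite(dra)) stopf("DRA must be defined to flag CNV state")
  out_of_band <- function(x) is.finite(x) & (x < 0.8 | x > 1.2)
  out_of_band(dra) | out_of_band(drf)
}

#' Assign a read-depth genotype from DRA
#'
#' DRA in [0.2, 0.8) or (1.2, 1.75] is heterozygous `0/1`; DRA < 0.2 or
#' > 1.75 is homozygous `1/1`; the copy-neutral band [0.8, 1.2] yields no
#' CNV genotype (`./.`).
#'
#' @param dra Depth ratio(s) to the genome average; vectorized.
#' @return Character vector of genotypes in `{0/1, 1/1, ./.}`.
#' @export
assign_genotype <- function(dra) {
  stopifnot(all(dra >= 0))
  ifelse(dra < 0.2, "1/1",
    ifelse(dra < 0.8, "0/1",
      ifelse(dra <= 1.2, "./.",
        ifelse(dra <= 1.75, "0/1", "1/1"))))
}

#' Copy-number point estimate from DRA and chromosomal ploidy
#'
#' @param dra Depth ratio.
#' @param ploidy Chromosomal ploidy (2 for autosomes).
#' @return Integer copy number, `round(dra * ploidy)`.
#' @export
copy_number_estimate <- function(dra, ploidy = 2) as.integer(round(dra * ploidy))

#' Population coverage standard deviation track
#'
#' Per 1-kb interval, the population standard deviation (divide by N) of
#' DRA across control samples sharing the same interval grid.
#'
#' @param dra_matrix Numeric matrix, samples in rows, adjacent 1-kb
#'   intervals in columns (one contig), or a named list of such matrices.
#' @return Numeric vector (or named list of vectors) of per-interval SDs.
#' @export
population_coverage_sd <- function(dra_matrix) {
  if (is.list(dra_matrix) && !is.matrix(dra_matrix)) {
    return(lapply(dra_matrix, population_coverage_sd))
  }
  stopifnot(is.matrix(dra_matrix))
  mu <- colMeans(dra_matrix)
  sqrt(pmax(0, colMeans(dra_matrix^2) - mu^2))  # population SD (divide by N)
}

#' Write / read a coverage track as fixed-step wiggle
#'
#' Plain-text fixedStep wiggle keyed on the track's bin size; the MQ layer
#' is written as a companion `*.mq.wig` file.
#'
#' @param track Coverage track.
#' @param path Output wiggle path.
#' @param contig_lengths Named vector of contig lengths (reader only).
#' @return The path (writer) or a [coverage_track()] (reader).
#' @export
write_coverage_wig <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  mq_path <- paste0(sub("\\.wig$", "", path), ".mq.wig")
  con2 <- file(mq_path, "w")
  on.exit(close(con2), add = TRUE)
  for (ctg in names(track$contigs)) {
    hdr <- sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                   ctg, track$bin_size, track$bin_size)
    writeLines(hdr, con)
    writeLines(format(track$contigs[[ctg]]$depth, trim = TRUE, digits = 8,
                      scientific = FALSE), con)
    writeLines(hdr, con2)
    writeLines(format(track$contigs[[ctg]]$mq, trim = TRUE, digits = 8,
                      scientific = FALSE), con2)
  }
  invisible(path)
}

#' @rdname write_coverage_wig
#' @export
read_coverage_wig <- function(path, contig_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "wig")
  mq_path <- paste0(sub("\\.wig$", "", path), ".mq.wig")
  grq <- if (file.exists(mq_path)) rtracklayer::import(mq_path, format = "wig") else NULL
  bs <- as.integer(GenomicRanges::width(gr)[1])
  ctgs <- unique(as.character(GenomicRanges::seqnames(gr)))
  depth <- lapply(ctgs, function(ctg) {
    gr[GenomicRanges::seqnames(gr) == ctg]$score
  })
  names(depth) <- ctgs
  mq <- NULL
  if (!is.null(grq)) {
    mq <- lapply(ctgs, function(ctg) grq[GenomicRanges::seqnames(grq) == ctg]$score)
    names(mq) <- ctgs
  }
  coverage_track(depth, mq, bin_size = bs, contig_lengths = contig_lengths)
}
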