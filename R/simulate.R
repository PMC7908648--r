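# Synthetic-data generator: toy genomes with planted DEL/DUP/INV truth
# sets, per-sample evidence (coverage/MQ tracks, DP and SR records),
# caller-style candidate call files and control cohorts with configurable
# allele frequencies. Evidence is simulated at the DP/SR/coverage level —
# no reads or aligner — which exercises every downstream formula while
# keeping simulation fast and fully reproducible.

#' Simulation configuration
#'
#' @param contig_lengths Named numeric vector of contig lengths (default a
#'   single 5-Mb contig "ctg1").
#' @param variants Data frame of planted variants: `chrom`, `start`, `end`,
#'   `svtype` (DEL/DUP/INV) and either `genotype` ("0/1"/"1/1") for
#'   single-sample use or `af` (cohort allele frequency) for cohorts.
#'   Variants must not overlap and must keep a 5-kb flanking spacing.
#' @param depth Haploid-pair average coverage (default 30).
#' @param read_length Read length in bases (default 150).
#' @param fragment_mean,fragment_sd Fragment-length distribution
#'   (default 450 +/- 75).
#' @param bin_size Coverage-track bin width (default 100).
#' @param mq_high Baseline average mapping quality (default 60).
#' @param low_mq_regions Optional data frame (`chrom`, `start`, `end`,
#'   `mq`) of low-mappability patches; SR/DP generation is suppressed and
#'   the MQ track depressed there.
#' @param spacing Required flank between planted variants (default 5000).
#' @param seed Integer seed; a fixed seed makes all outputs reproducible.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(contig_lengths = c(ctg1 = 5e6), variants = NULL,
                       depth = 30, read_length = 150, fragment_mean = 450,
                       fragment_sd = 75, bin_size = 100L, mq_high = 60,
                       low_mq_regions = NULL, spacing = 5000, seed = 1L) {
  if (is.null(variants)) {
    variants <- data.frame(chrom = character(), start = integer(),
                           end = integer(), svtype = character(),
                           genotype = character(), stringsAsFactors = FALSE)
  }
  need_cols(variants, c("chrom", "start", "end", "svtype"), "planted variants")
  if (nrow(variants) > 1) {
    for (ctg in unique(variants$chrom)) {
      v <- variants[variants$chrom == ctg, , drop = FALSE]
      v <- v[order(v$start), , drop = FALSE]
      if (nrow(v) > 1 && any(v$start[-1] - v$end[-nrow(v)] <= spacing)) {
        stopf("planted variants on %s overlap or violate %d-bp spacing",
              ctg, spacing)
      }
    }
  }
  if (any(variants$end > contig_lengths[variants$chrom] |
          variants$start < 1)) {
    stopf("planted variant outside contig bounds")
  }
  structure(list(contig_lengths = contig_lengths, variants = variants,
                 depth = depth, read_length = read_length,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 bin_size = as.integer(bin_size), mq_high = mq_high,
                 low_mq_regions = low_mq_regions, spacing = spacing,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Copy number on the simulated diploid for a genotype and svtype
#' @noRd
sim_copy_number <- function(svtype, genotype) {
  alt <- switch(svtype, DEL = -1, DUP = +1, 0)
  nalt <- ifelse(genotype == "1/1", 2, ifelse(genotype == "0/1", 1, 0))
  2 + alt * nalt
}

#' Simulate one sample's evidence set
#'
#' Produces a coverage/MQ track whose depth reflects the planted copy
#' states (het DEL ~ 0.5x, hom DEL ~ 0x, het DUP ~ 1.5x of baseline) with
#' Poisson-like per-bin noise, plus DP and SR records clustered at the
#' planted breakpoints with counts proportional to depth and allele
#' fraction and orientation determined by the SV type (DEL: FR, DUP: RF,
#' INV: FF/RR). Low-MQ patches depress the MQ track and suppress evidence.
#'
#' @param config A [sim_config()].
#' @param sample_id Sample name.
#' @param genotypes Optional character vector overriding
#'   `config$variants$genotype` (one per planted variant; "0/0" plants
#'   nothing for that sample).
#' @return List of class `evidence_set`: `track` ([coverage_track()]),
#'   `dp`, `sr` (evidence data frames), `truth` (the planted-variant table
#'   with `genotype` and `carried`), `sample_id`, `config`.
#' @export
simulate_sample <- function(config, sample_id = "S1", genotypes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  v <- config$variants
  if (!is.null(genotypes)) {
    stopifnot(length(genotypes) == nrow(v))
    v$genotype <- genotypes
  }
  if (is.null(v$genotype) && nrow(v)) v$genotype <- "0/1"
  withr_seed <- derive_seed(config$seed, sum(utf8ToInt(sample_id)))
  old <- globalenv()$.Random.seed
  set.seed(withr_seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  bs <- config$bin_size
  reads_per_bin <- config$depth * bs / config$read_length
  depth_list <- list(); mq_list <- list()
  for (ctg in names(config$contig_lengths)) {
    nbins <- ceiling(config$contig_lengths[[ctg]] / bs)
    cn <- rep(2, nbins)
    vc <- v[v$chrom == ctg & v$svtype %in% c("DEL", "DUP") &
              v$genotype %in% c("0/1", "1/1"), , drop = FALSE]
    for (i in seq_len(nrow(vc))) {
      b1 <- (vc$start[i] - 1) %/% bs + 1
      b2 <- min(nbins, (vc$end[i] - 1) %/% bs + 1)
      cn[b1:b2] <- sim_copy_number(vc$svtype[i], vc$genotype[i])
    }
    lam <- reads_per_bin * cn / 2
    depth_list[[ctg]] <- stats::rpois(nbins, lam) * config$read_length / bs
    mq <- rep(config$mq_high, nbins)
    lq <- config$low_mq_regions
    if (!is.null(lq)) {
      lqc <- lq[lq$chrom == ctg, , drop = FALSE]
      for (i in seq_len(nrow(lqc))) {
        b1 <- (lqc$start[i] - 1) %/% bs + 1
        b2 <- min(nbins, (lqc$end[i] - 1) %/% bs + 1)
        mq[b1:b2] <- lqc$mq[i]
      }
    }
    mq_list[[ctg]] <- mq
  }
  track <- coverage_track(depth_list, mq_list, bin_size = bs,
                          contig_lengths = config$contig_lengths)

  dp <- sr <- NULL
  carried <- rep(FALSE, nrow(v))
  for (i in seq_len(nrow(v))) {
    gt <- v$genotype[i]
    if (!gt %in% c("0/1", "1/1")) next
    if (in_low_mq(config, v$chrom[i], v$start[i]) &&
        in_low_mq(config, v$chrom[i], v$end[i])) next
    carried[i] <- TRUE
    af <- if (gt == "1/1") 1 else 0.5
    orient <- switch(v$svtype[i], DEL = "FR", DUP = "RF", INV = "FF")
    n_dp <- stats::rpois(1, config$depth * af)
    n_sr <- stats::rpois(1, config$depth * af / 2)
    gap <- max(config$fragment_mean - 2 * config$read_length, 10)
    if (n_dp > 0) {
      off1 <- sample.int(gap, n_dp, replace = TRUE)
      off2 <- sample.int(gap, n_dp, replace = TRUE)
      dp <- rbind(dp, data.frame(
        chrom = v$chrom[i], start = v$start[i] - off1, end = v$end[i] + off2,
        mate_chrom = v$chrom[i], orientation = orient,
        mapq = config$mq_high, sample_id = sample_id,
        stringsAsFactors = FALSE))
    }
    if (n_sr > 0) {
      sr <- rbind(sr, data.frame(
        chrom = v$chrom[i], start = rep(v$start[i], n_sr), end = v$end[i],
        mate_chrom = v$chrom[i], orientation = orient,
        mapq = config$mq_high, sample_id = sample_id,
        stringsAsFactors = FALSE))
    }
  }
  proto <- data.frame(chrom = character(), start = integer(), end = integer(),
                      mate_chrom = character(), orientation = character(),
                      mapq = numeric(), sample_id = character(),
                      stringsAsFactors = FALSE)
  dp <- dp %||% proto; sr <- sr %||% proto
  ord <- order(dp$chrom, dp$start); dp <- dp[ord, , drop = FALSE]
  ord <- order(sr$chrom, sr$start); sr <- sr[ord, , drop = FALSE]
  rownames(dp) <- rownames(sr) <- NULL
  v$carried <- carried
  structure(list(track = track, dp = dp, sr = sr, truth = v,
                 sample_id = sample_id, config = config),
            class = "evidence_set")
}

in_low_mq <- function(config, chrom, pos) {
  lq <- config$low_mq_regions
  if (is.null(lq)) return(FALSE)
  any(lq$chrom == chrom & lq$start <= pos & lq$end >= pos)
}

#' @export
print.evidence_set <- function(x, ...) {
  cat(sprintf("evidence_set %s: %d DP, %d SR, %d planted variant(s)\n",
              x$sample_id, nrow(x$dp), nrow(x$sr), nrow(x$truth)))
  invisible(x)
}

#' Simulate a control cohort and build its evidence database
#'
#' Carriers are drawn binomially per variant at the configured cohort
#' allele (carrier) frequency; carriers are heterozygous unless
#' `hom_fraction` promotes some to homozygous. The database aggregates carrier DP/SR breakpoint evidence, per-sample
#' 1-kb DRA summaries (Gaussian noise, sd `dra_sd`, around the copy-state
#' expectation) and the Pass/High control variant set with carrier counts.
#'
#' @param config A [sim_config()]; `config$variants$af` supplies the
#'   cohort allele frequencies (absent column = AF 0).
#' @param n_samples Cohort size (default 100).
#' @param dra_sd Per-interval DRA noise SD (default 0.1).
#' @param hom_fraction Fraction of carriers drawn homozygous (default 0).
#' @return List of class `sim_cohort`: `db` ([control_db()]),
#'   `carrier_counts` (per planted variant), `genotype_matrix`
#'   (variant x sample).
#' @export
simulate_cohort <- function(config, n_samples = 100, dra_sd = 0.1,
                            hom_fraction = 0) {
  stopifnot(inherits(config, "sim_config"))
  v <- config$variants
  af <- v$af %||% rep(0, nrow(v))
  old <- globalenv()$.Random.seed
  set.seed(derive_seed(config$seed, 7919L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  nv <- nrow(v)
  gt <- matrix("0/0", nrow = nv, ncol = n_samples)
  if (nv) {
    for (i in seq_len(nv)) {
      carrier <- stats::rbinom(n_samples, 1, af[i]) == 1
      hom <- carrier & stats::runif(n_samples) < hom_fraction
      gt[i, carrier] <- "0/1"
      gt[i, hom] <- "1/1"
    }
  }
  carrier_counts <- if (nv) rowSums(gt != "0/0") else integer(0)

  # 1-kb DRA summaries per contig: samples x intervals
  dra <- list()
  for (ctg in names(config$contig_lengths)) {
    nint <- ceiling(config$contig_lengths[[ctg]] / 1000)
    m <- matrix(stats::rnorm(n_samples * nint, 1, dra_sd),
                nrow = n_samples, ncol = nint)
    vc <- which(v$chrom == ctg & v$svtype %in% c("DEL", "DUP"))
    for (i in vc) {
      i1 <- (v$start[i] - 1) %/% 1000 + 1
      i2 <- min(nint, (v$end[i] - 1) %/% 1000 + 1)
      for (s in seq_len(n_samples)) {
        cnr <- sim_copy_number(v$svtype[i], gt[i, s]) / 2
        if (cnr != 1) {
          m[s, i1:i2] <- stats::rnorm(i2 - i1 + 1, cnr, dra_sd)
        }
      }
    }
    dra[[ctg]] <- pmax(m, 0)
  }

  # breakpoint evidence tables: per carrier, counts at each breakpoint
  brk <- function(kind) {
    rows <- NULL
    for (i in seq_len(nv)) {
      carr <- gt[i, ] != "0/0"
      if (!any(carr)) next
      af_s <- ifelse(gt[i, carr] == "1/1", 1, 0.5)
      lam <- if (kind == "dp") config$depth * af_s else config$depth * af_s / 2
      counts <- stats::rpois(sum(carr), lam)
      orient <- switch(v$svtype[i], DEL = "FR", DUP = "RF", INV = "FF")
      for (pos in c(v$start[i], v$end[i])) {
        rows <- rbind(rows, data.frame(
          chrom = v$chrom[i], pos = pos, orientation = orient,
          count = sum(counts), sample_count = sum(counts > 0),
          stringsAsFactors = FALSE))
      }
    }
    rows
  }
  dp_brkp <- brk("dp"); sr_brkp <- brk("sr")

  cv <- NULL
  if (nv) {
    cv <- data.frame(chrom = v$chrom, start = v$start, end = v$end,
                     svtype = v$svtype,
                     cnv = v$svtype %in% c("DEL", "DUP"),
                     carriers = carrier_counts, stringsAsFactors = FALSE)
    cv <- cv[cv$carriers > 0, , drop = FALSE]
  }
  db <- control_db(n_samples, sr_brkp = sr_brkp, dp_brkp = dp_brkp,
                   dra_1kb = dra, variants = cv)
  structure(list(db = db, carrier_counts = carrier_counts,
                 genotype_matrix = gt, config = config),
            class = "sim_cohort")
}

#' Emit caller-style candidate calls from a truth table
#'
#' doc-style calls are quantized to 100-base bins (boundaries are
#' multiples of the bin) with optional jitter, restricted to CNV types;
#' srdp-style calls sit at the exact breakpoints (plus jitter) and carry
#' SU counts. Optional dropout removes a fraction of calls to exercise
#' single-caller paths.
#'
#' @param truth Planted-variant data frame (`chrom`, `start`, `end`,
#'   `svtype`, optional `genotype`).
#' @param style "doc" or "srdp".
#' @param jitter SD in bases of boundary jitter (default 0).
#' @param dropout Probability of dropping each call (default 0).
#' @param sample_id Sample carrying the evidence counts.
#' @param depth Depth used to draw SU counts for srdp-style calls.
#' @param seed Seed for jitter/dropout/SU draws.
#' @return A [call_set()].
#' @export
emit_candidate_calls <- function(truth, style = c("doc", "srdp"), jitter = 0,
                                 dropout = 0, sample_id = "S1", depth = 30,
                                 seed = 1L) {
  style <- match.arg(style)
  old <- globalenv()$.Random.seed
  set.seed(derive_seed(seed, if (style == "doc") 11L else 13L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  tr <- truth
  if (style == "doc") tr <- tr[tr$svtype %in% c("DEL", "DUP"), , drop = FALSE]
  if (dropout > 0 && nrow(tr)) {
    tr <- tr[stats::runif(nrow(tr)) >= dropout, , drop = FALSE]
  }
  if (nrow(tr) == 0) {
    return(call_set(data.frame(chrom = character(), start = integer(),
                               end = integer(), svtype = character(),
                               caller = character(), stringsAsFactors = FALSE)))
  }
  jit <- function(x) x + if (jitter > 0) round(stats::rnorm(length(x), 0, jitter)) else 0
  if (style == "doc") {
    start <- pmax(1, round(jit(tr$start) / 100) * 100 + 1)
    end <- pmax(start + 99, round(jit(tr$end) / 100) * 100)
  } else {
    start <- pmax(1, jit(tr$start))
    end <- pmax(start + 1, jit(tr$end))
  }
  calls <- data.frame(chrom = tr$chrom, start = start, end = end,
                      svtype = tr$svtype, caller = style,
                      stringsAsFactors = FALSE)
  cs <- call_set(calls)
  if (style == "srdp") {
    gt <- tr$genotype %||% rep("0/1", nrow(tr))
    af <- ifelse(gt == "1/1", 1, 0.5)
    sr <- stats::rpois(nrow(tr), depth * af / 2)
    dp <- stats::rpois(nrow(tr), depth * af)
    cs$samples <- data.frame(id = cs$calls$id, sample_id = sample_id,
                             sr = sr, dp = dp, su = sr + dp,
                             stringsAsFactors = FALSE)
  }
  cs
}

#' Naive fixed-bin depth segmenter (fixture-only caller stand-in)
#'
#' Thresholds the DRA track at the CNV band (loss < 0.8, gain > 1.2) using
#' a running median over `smooth` bins and reports maximal runs of at
#' least `min_bins` bins as doc-style DEL/DUP candidate calls. This exists
#' only to derive doc-caller-shaped input from simulated tracks; it is not
#' a reimplementation of any published caller.
#'
#' @param track Coverage track.
#' @param genome_est Genome baseline ([estimate_genome_coverage()]).
#' @param min_bins Minimum run length in bins (default 10).
#' @param smooth Running-median window in bins (odd, default 9).
#' @return A [call_set()] with caller "doc".
#' @export
naive_doc_segmenter <- function(track, genome_est, min_bins = 10, smooth = 9) {
  calls <- NULL
  for (ctg in names(track$contigs)) {
    base <- baseline_for(genome_est, ctg)
    dra <- track$contigs[[ctg]]$depth / base
    if (length(dra) > smooth) dra <- stats::runmed(dra, smooth)
    state <- ifelse(dra < 0.8, "DEL", ifelse(dra > 1.2, "DUP", "N"))
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    idx <- which(r$values != "N" & r$lengths >= min_bins)
    if (length(idx)) {
      calls <- rbind(calls, data.frame(
        chrom = ctg,
        start = (starts[idx] - 1L) * track$bin_size + 1L,
        end = pmin(ends[idx] * track$bin_size, track$contigs[[ctg]]$length),
        svtype = r$values[idx], caller = "doc", stringsAsFactors = FALSE))
    }
  }
  if (is.null(calls)) {
    calls <- data.frame(chrom = character(), start = integer(),
                        end = integer(), svtype = character(),
                        caller = character(), stringsAsFactors = FALSE)
  }
  call_set(calls)
}

#' Randomly place non-overlapping variants on a toy genome
#'
#' Draws `n` variants with log-uniform sizes in `[min_size, max_size]`,
#' alternating DEL/DUP (or sampled from `svtypes`), left to right with at
#' least `spacing` bases between consecutive variants.
#'
#' @param contig_lengths Named vector of contig lengths.
#' @param n Number of variants.
#' @param min_size,max_size Size range in bases.
#' @param svtypes Types to draw from.
#' @param spacing Minimum flank between variants (default 5000).
#' @param seed Seed.
#' @return Planted-variant data frame.
#' @export
place_random_variants <- function(contig_lengths, n, min_size = 500,
                                  max_size = 500000,
                                  svtypes = c("DEL", "DUP"), spacing = 5000,
                                  seed = 1L) {
  old <- globalenv()$.Random.seed
  set.seed(derive_seed(seed, 23L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  sizes <- round(exp(stats::runif(n, log(min_size), log(max_size))))
  types <- sample(svtypes, n, replace = TRUE)
  total <- sum(as.numeric(contig_lengths))
  if (sum(sizes) + (n + 1) * spacing > 0.9 * total) {
    stopf("requested variants do not fit the genome with %d-bp spacing", spacing)
  }
  # distribute variants across contigs proportionally, then place with
  # random gaps >= spacing
  out <- NULL
  remaining <- data.frame(size = sizes, svtype = types,
                          stringsAsFactors = FALSE)
  ctgs <- names(contig_lengths)
  share <- as.numeric(contig_lengths) / total
  counts <- diff(round(c(0, cumsum(share * n))))
  idx0 <- 1
  for (k in seq_along(ctgs)) {
    nk <- counts[k]
    if (nk == 0) next
    sub <- remaining[idx0:(idx0 + nk - 1), , drop = FALSE]
    idx0 <- idx0 + nk
    len <- contig_lengths[[k]]
    slack <- len - sum(sub$size) - (nk + 1) * spacing
    if (slack < 0) stopf("variants do not fit contig %s", ctgs[k])
    gaps <- stats::rmultinom(1, max(0, round(slack / 1000)), rep(1, nk + 1)) * 1000
    pos <- spacing + gaps[1]
    for (i in seq_len(nk)) {
      out <- rbind(out, data.frame(chrom = ctgs[k], start = pos + 1,
                                   end = pos + sub$size[i],
                                   svtype = sub$svtype[i],
                                   stringsAsFactors = FALSE))
      pos <- pos + sub$size[i] + spacing + gaps[i + 1]
    }
  }
  rownames(out) <- NULL
  out
}
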