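# Control-cohort evidence database and the five population allele
# frequency (PAF) measures: PAFSU (raw DP+SR evidence), PAFDRA (read-depth
# concordance), PAFV (called control variants), PAF1KG and PAFG (external
# reference sets), plus the RARE flag.

#' Build a control-cohort evidence database
#'
#' The database holds, for `n_samples` controls: breakpoint-indexed SR and
#' DP count tables (columns `chrom`, `pos`, `orientation`, `count`,
#' `sample_count`), per-sample DRA summarized in adjacent 1-kb intervals
#' (a named list of sample x interval matrices, one per contig), and the
#' set of Pass/High control variants with carrier counts.
#'
#' @param n_samples Number of control samples (NCS, >= 1).
#' @param sr_brkp,dp_brkp Breakpoint count tables (may be empty).
#' @param dra_1kb Named list (per contig) of sample-by-interval DRA
#'   matrices on the fixed grid `[1,1000], [1001,2000], ...`.
#' @param variants Control variant data frame (`chrom`, `start`, `end`,
#'   `svtype`, `cnv`, `carriers`).
#' @return Object of class `control_db`.
#' @export
control_db <- function(n_samples, sr_brkp = NULL, dp_brkp = NULL,
                       dra_1kb = NULL, variants = NULL) {
  if (n_samples < 1) stopf("control cohort needs >= 1 sample")
  proto <- data.frame(chrom = character(), pos = integer(),
                      orientation = character(), count = integer(),
                      sample_count = integer(), stringsAsFactors = FALSE)
  vproto <- data.frame(chrom = character(), start = integer(), end = integer(),
                       svtype = character(), cnv = logical(),
                       carriers = integer(), stringsAsFactors = FALSE)
  db <- list(n_samples = as.integer(n_samples),
             sr_brkp = sr_brkp %||% proto,
             dp_brkp = dp_brkp %||% proto,
             dra_1kb = dra_1kb %||% list(),
             variants = variants %||% vproto)
  for (tb in c("sr_brkp", "dp_brkp")) {
    need_cols(db[[tb]], c("chrom", "pos", "orientation", "count"), tb)
    if (is.null(db[[tb]]$sample_count)) db[[tb]]$sample_count <- db[[tb]]$count
    db[[tb]] <- db[[tb]][order(db[[tb]]$chrom, db[[tb]]$pos), , drop = FALSE]
  }
  class(db) <- "control_db"
  db
}

#' @export
print.control_db <- function(x, ...) {
  cat(sprintf(paste0("control_db: %d samples, %d SR / %d DP breakpoint rows, ",
                     "%d contig DRA grids, %d control variants\n"),
              x$n_samples, nrow(x$sr_brkp), nrow(x$dp_brkp),
              length(x$dra_1kb), nrow(x$variants)))
  invisible(x)
}

#' Save / load a control database as plain tab-separated tables
#'
#' Writes `meta.tsv`, `SR.brkp.tsv`, `PE.brkp.tsv`, `variants.tsv` and one
#' `dra1kb.<contig>.tsv` per contig into a directory.
#'
#' @param db A [control_db()].
#' @param dir Directory path.
#' @return The directory (writer) or a `control_db` (reader).
#' @export
save_control_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data.frame(key = "n_samples", value = db$n_samples),
                     file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(db$sr_brkp, file.path(dir, "SR.brkp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(db$dp_brkp, file.path(dir, "PE.brkp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(db$variants, file.path(dir, "variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (ctg in names(db$dra_1kb)) {
    utils::write.table(db$dra_1kb[[ctg]],
                       file.path(dir, sprintf("dra1kb.%s.tsv", ctg)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_control_db
#' @export
load_control_db <- function(dir) {
  meta <- utils::read.table(file.path(dir, "meta.tsv"), header = TRUE, sep = "\t")
  rd <- function(f) utils::read.table(file.path(dir, f), header = TRUE,
                                      sep = "\t", stringsAsFactors = FALSE)
  dra_files <- list.files(dir, pattern = "^dra1kb\\..*\\.tsv$", full.names = TRUE)
  dra <- lapply(dra_files, function(f) as.matrix(utils::read.table(f, sep = "\t")))
  names(dra) <- sub("^dra1kb\\.(.*)\\.tsv$", "\\1", basename(dra_files))
  control_db(meta$value[meta$key == "n_samples"],
             sr_brkp = rd("SR.brkp.tsv"), dp_brkp = rd("PE.brkp.tsv"),
             dra_1kb = dra, variants = rd("variants.tsv"))
}

#' Control evidence count in the breakpoint windows of a variant (SUC)
#' @noRd
control_su <- function(db, chrom, start, end, svtype, flank = 1000) {
  one <- function(tb) {
    t2 <- tb[tb$chrom == chrom & orientation_matches(svtype, tb$orientation), ,
             drop = FALSE]
    if (nrow(t2) == 0) return(0)
    near5 <- abs(t2$pos - start) <= flank
    near3 <- abs(t2$pos - end) <= flank
    sum(t2$count[near5]) + sum(t2$count[near3])
  }
  one(db$sr_brkp) + one(db$dp_brkp)
}

#' Population allele frequency from raw control evidence (PAFSU)
#'
#' PAFSU = SUC / SU / NCS, where SU is the variant's supporting DP+SR
#' count, SUC the total of control DP/SR counts located within 1000 bases
#' of each breakpoint with orientation matching the SV type, and NCS the
#' number of control samples. For example, SU = 10 with SUC = 200 in a
#' 500-sample cohort gives PAFSU = 0.04 (4%). PAFSU is an abundance
#' estimate and can exceed 1.
#'
#' @param su Supporting DP+SR count of the variant (> 0).
#' @param chrom,start,end,svtype Variant interval and type.
#' @param db A [control_db()].
#' @param flank Breakpoint window in bases (default 1000).
#' @return Numeric fraction (>= 0), or `NA` when `su` is 0.
#' @export
compute_pafsu <- function(su, chrom, start, end, svtype, db, flank = 1000) {
  if (is.na(su) || su <= 0) return(NA_real_)
  suc <- control_su(db, chrom, start, end, svtype, flank)
  suc / su / db$n_samples
}

#' Population allele frequency from read-depth concordance (PAFDRA)
#'
#' Counts the control samples showing the same direction of copy-number
#' change (loss: DRA < 0.8; gain: DRA > 1.2) over at least 90% of the
#' CNV's overlapped 1-kb intervals, divided by the cohort size. A CNV
#' shorter than one interval uses its single overlapping interval.
#'
#' @param chrom,start,end Variant interval.
#' @param direction "loss" or "gain".
#' @param db A [control_db()] with 1-kb DRA summaries.
#' @param min_fraction Required fraction of concordant intervals (0.9).
#' @return Numeric fraction in \[0, 1\], or `NA` when the contig has no
#'   DRA summary.
#' @export
compute_pafdra <- function(chrom, start, end, direction = c("loss", "gain"),
                           db, min_fraction = 0.9) {
  direction <- match.arg(direction)
  m <- db$dra_1kb[[chrom]]
  if (is.null(m)) return(NA_real_)
  i1 <- (start - 1) %/% 1000 + 1
  i2 <- (end - 1) %/% 1000 + 1
  i2 <- min(i2, ncol(m)); i1 <- min(i1, i2)
  sub <- m[, i1:i2, drop = FALSE]
  conc <- if (direction == "loss") sub < 0.8 else sub > 1.2
  carrier <- rowMeans(conc) >= min_fraction
  sum(carrier) / db$n_samples
}

#' Match a query variant against a reference variant
#'
#' The SV type and CNV state must already agree (checked by the caller or
#' via `svtype`/`cnv` columns). Copy-number-neutral SVs match when both
#' breakpoints deviate by at most `breakpoint_tol` bases. CNVs of at least
#' 1 kb match when the overlap covers at least 20% of the reference
#' variant's length and at least 90% of the query's; query CNVs shorter
#' than 1 kb require at least 70% of the query length (the 20%-of-reference
#' clause is retained).
#'
#' @param q,r One-row variants (list/data frame) with `chrom`, `start`,
#'   `end`, `svtype` and logical `cnv`.
#' @param breakpoint_tol Breakpoint tolerance in bases (default 1000).
#' @return Logical.
#' @export
match_variant <- function(q, r, breakpoint_tol = 1000) {
  q <- as.list(q); r <- as.list(r)
  if (q$chrom != r$chrom || q$svtype != r$svtype) return(FALSE)
  qcnv <- isTRUE(q$cnv); rcnv <- isTRUE(r$cnv)
  if (qcnv != rcnv) return(FALSE)
  if (!qcnv) {
    return(abs(q$start - r$start) <= breakpoint_tol &&
           abs(q$end - r$end) <= breakpoint_tol)
  }
  ov <- iv_overlap(q$start, q$end, r$start, r$end)
  qlen <- q$end - q$start + 1
  rlen <- r$end - r$start + 1
  if (ov < 0.2 * rlen) return(FALSE)
  if (qlen < 1000) ov >= 0.7 * qlen else ov >= 0.9 * qlen
}

#' Population allele frequency from called control variants (PAFV)
#'
#' Matches the query against the database's Pass/High control variants
#' with [match_variant()]; the carrier count of the best match (largest
#' overlap) divided by the cohort size. 0 when nothing matches.
#'
#' @param q One-row variant with `chrom`, `start`, `end`, `svtype`, `cnv`.
#' @param db A [control_db()].
#' @return Numeric fraction in \[0, 1\].
#' @export
compute_pafv <- function(q, db) {
  best <- best_matching_record(q, db$variants)
  if (is.null(best)) return(0)
  best$carriers / db$n_samples
}

#' Population allele frequency from an external reference set
#'
#' Matches against a reference set (e.g. a population SV release) carrying
#' an `af` column; returns the best-matching record's allele frequency,
#' 0 when nothing matches.
#'
#' @param q One-row variant.
#' @param ref_set Data frame with `chrom`, `start`, `end`, `svtype`, `cnv`,
#'   `af`.
#' @return Numeric allele frequency.
#' @export
compute_external_paf <- function(q, ref_set) {
  best <- best_matching_record(q, ref_set)
  if (is.null(best)) return(0)
  best$af
}

#' Best match_variant() hit by overlap length
#' @noRd
best_matching_record <- function(q, refs) {
  if (is.null(refs) || nrow(refs) == 0) return(NULL)
  q <- as.list(q)
  cand <- refs[refs$chrom == q$chrom & refs$svtype == q$svtype, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  ok <- vapply(seq_len(nrow(cand)), function(i) match_variant(q, cand[i, ]),
               logical(1))
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  ov <- iv_overlap(cand$start, cand$end, q$start, q$end)
  cand[which.max(ov), , drop = FALSE]
}

#' Matched DGV-style records for a variant (same matching rules as PAF1KG)
#'
#' @param q One-row variant.
#' @param dgv Data frame with `id`, `chrom`, `start`, `end`, `svtype`, `cnv`.
#' @return Character vector of matched record ids (possibly empty).
#' @export
match_dgv <- function(q, dgv) {
  if (is.null(dgv) || nrow(dgv) == 0) return(character())
  ok <- vapply(seq_len(nrow(dgv)), function(i) match_variant(q, dgv[i, ]),
               logical(1))
  as.character(dgv$id[ok])
}

#' Rare-variant flag from a PAF set
#'
#' A variant is common when any of PAFV, PAFSU, PAFDRA or PAF1KG exceeds
#' 0.01 (strictly); otherwise it is rare. Missing values count as 0. The
#' gnomAD-style PAFG is annotation-only and excluded from the rule.
#'
#' @param pafv,pafsu,pafdra,paf1kg PAF values (may be `NA`).
#' @param threshold Commonness threshold (default 0.01, strict >).
#' @return Logical: `TRUE` when rare.
#' @export
flag_rare <- function(pafv = NA, pafsu = NA, pafdra = NA, paf1kg = NA,
                      threshold = 0.01) {
  v <- c(pafv, pafsu, pafdra, paf1kg)
  v[is.na(v)] <- 0
  !any(v > threshold)
}
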