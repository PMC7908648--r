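# End-to-end orchestration: take candidate calls from the two callers plus
# per-sample evidence, and produce fully annotated integrated variants.

#' Annotate every call in a set with depth-of-coverage metrics
#'
#' Adds `doc`, `dra`, `drf`, `avg_mq`, `gt`, `copy_number` and a
#' per-sample `cnv` column to the call set's sample table (creating rows
#' for `sample_id` when the caller supplied none).
#'
#' @param cs A [call_set()].
#' @param track Coverage track for the sample.
#' @param genome_est Genome baseline estimate.
#' @param sample_id Sample the track belongs to.
#' @return The call set with an enriched sample table.
#' @export
annotate_doc_metrics <- function(cs, track, genome_est, sample_id) {
  stopifnot(inherits(cs, "call_set"))
  calls <- cs$calls
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    m <- compute_doc_metrics(calls$chrom[i], calls$start[i], calls$end[i],
                             track, genome_est)
    data.frame(id = calls$id[i], sample_id = sample_id,
               doc = m$doc, dra = m$dra, drf = m$drf, avg_mq = m$avg_mq,
               gt = assign_genotype(m$dra),
               copy_number = copy_number_estimate(
                 m$dra, ploidy_for(genome_est, calls$chrom[i])),
               cnv = flag_cnv(m$dra, m$drf), stringsAsFactors = FALSE)
  })
  docm <- do.call(rbind, rows)
  if (is.null(docm)) return(cs)
  sm <- cs$samples
  key_old <- paste(sm$id, sm$sample_id)
  key_new <- paste(docm$id, docm$sample_id)
  merged <- rbind_fill(sm[!(key_old %in% key_new), , drop = FALSE],
                       merge_doc_rows(sm, docm, key_old, key_new))
  cs$samples <- merged %||% docm
  cs$samples$su <- (cs$samples$sr %|NA|% 0L) + (cs$samples$dp %|NA|% 0L)
  cs
}

`%|NA|%` <- function(x, v) { if (is.null(x)) return(v); ifelse(is.na(x), v, x) }

merge_doc_rows <- function(sm, docm, key_old, key_new) {
  add <- docm[!(key_new %in% key_old), , drop = FALSE]
  upd <- docm[key_new %in% key_old, , drop = FALSE]
  if (nrow(upd)) {
    base <- sm[match(paste(upd$id, upd$sample_id), key_old), , drop = FALSE]
    for (cl in c("doc", "dra", "drf", "avg_mq", "gt", "copy_number", "cnv")) {
      base[[cl]] <- upd[[cl]]
    }
    return(rbind_fill(base, add))
  }
  rbind_fill(add)
}

#' Annotate doc-caller calls with read evidence from DP/SR records
#'
#' Applies [annotate_doc_call_with_read_evidence()] to every call and
#' merges the per-sample counts into the sample table.
#'
#' @param cs A [call_set()] of doc-caller calls.
#' @param dp,sr Evidence data frames.
#' @return The enriched call set.
#' @export
annotate_read_evidence <- function(cs, dp, sr) {
  rows <- lapply(seq_len(nrow(cs$calls)), function(i) {
    cnt <- annotate_doc_call_with_read_evidence(cs$calls[i, ], dp, sr)
    if (nrow(cnt)) cnt$id <- cs$calls$id[i]
    cnt
  })
  counts <- do.call(rbind, Filter(nrow, rows))
  if (is.null(counts) || nrow(counts) == 0) return(cs)
  sm <- cs$samples
  key_old <- paste(sm$id, sm$sample_id)
  key_new <- paste(counts$id, counts$sample_id)
  upd_idx <- match(key_old, key_new)
  for (cl in c("sr", "dp")) {
    have <- !is.na(upd_idx)
    if (!cl %in% names(sm)) sm[[cl]] <- 0L
    sm[[cl]][have] <- pmax(sm[[cl]][have] %|NA|% 0L, counts[[cl]][upd_idx[have]])
  }
  add <- counts[!(key_new %in% key_old), , drop = FALSE]
  sm <- rbind_fill(sm, add)
  sm$su <- (sm$sr %|NA|% 0L) + (sm$dp %|NA|% 0L)
  cs$samples <- sm
  cs
}

#' Integrate one sample (or joint batch) end to end
#'
#' Runs the integration pipeline on candidate calls from a doc-style and
#' an srdp-style caller: masked-region splitting, DOC annotation of both
#' call sets, read-evidence annotation of doc calls, cross-sample merging
#' of doc calls, doc-with-srdp merging, mixed-support splitting, CNV
#' flagging and tranche classification.
#'
#' @param doc_cs,srdp_cs Candidate [call_set()]s.
#' @param tracks Named list of coverage tracks, one per sample.
#' @param genome_est Genome baseline (shared across the batch).
#' @param mask Optional masked-region data frame.
#' @param dp,sr Evidence data frames (all samples pooled).
#' @return List with `variants` (wide per-variant data frame: interval,
#'   svtype, caller, cnv, tranche, max su/sr/dp, mean avg_mq) and
#'   `samples` (long per-sample table).
#' @export
integrate_sample <- function(doc_cs, srdp_cs, tracks, genome_est,
                             mask = NULL, dp = NULL, sr = NULL) {
  if (!is.null(mask) && nrow(mask)) {
    doc_cs <- split_calls_at_mask(doc_cs, mask)
  }
  for (s in names(tracks)) {
    doc_cs <- annotate_doc_metrics(doc_cs, tracks[[s]], genome_est, s)
    srdp_cs <- annotate_doc_metrics(srdp_cs, tracks[[s]], genome_est, s)
  }
  if (!is.null(dp) || !is.null(sr)) {
    doc_cs <- annotate_read_evidence(doc_cs, dp, sr)
  }
  doc_cs <- merge_doc_calls_across_samples(doc_cs)
  merged <- merge_doc_with_srdp(doc_cs, srdp_cs)

  sm_by_id <- split(merged$samples, merged$samples$id)
  acc_calls <- list(); acc_samples <- list()
  for (i in seq_len(nrow(merged$calls))) {
    call <- merged$calls[i, , drop = FALSE]
    sm <- sm_by_id[[call$id]]
    if (is.null(sm)) sm <- merged$samples[0L, , drop = FALSE]
    pieces <- split_mixed_support(call, sm)
    for (p in pieces) {
      v <- p$call
      v$cnv <- p$cnv
      len <- v$end - v$start + 1
      psm <- p$samples
      su <- if (nrow(psm)) max(psm$su, na.rm = TRUE) else 0L
      srn <- if (nrow(psm) && !is.null(psm$sr)) max(psm$sr %|NA|% 0L) else 0L
      dpn <- if (nrow(psm) && !is.null(psm$dp)) max(psm$dp %|NA|% 0L) else 0L
      mq <- if (nrow(psm) && !is.null(psm$avg_mq)) {
        suppressWarnings(mean(psm$avg_mq, na.rm = TRUE))
      } else NA_real_
      v$su <- su; v$sr <- srn; v$dp <- dpn; v$avg_mq <- mq
      v$tranche <- classify_confidence(len, p$cnv, su, srn, dpn, mq)
      acc_calls[[length(acc_calls) + 1L]] <- v
      acc_samples[[length(acc_samples) + 1L]] <- psm
    }
  }
  out_calls <- do.call(rbind_fill, acc_calls)
  out_samples <- do.call(rbind_fill, acc_samples)
  if (is.null(out_calls)) {
    out_calls <- cbind(merged$calls,
                       data.frame(cnv = logical(0), su = integer(0),
                                  sr = integer(0), dp = integer(0),
                                  avg_mq = numeric(0), tranche = character(0)))
  }
  if (is.null(out_samples)) out_samples <- merged$samples
  ord <- order(out_calls$chrom, out_calls$start)
  list(variants = out_calls[ord, , drop = FALSE], samples = out_samples)
}

#' Attach population allele frequencies and the RARE flag
#'
#' Computes PAFSU, PAFDRA and PAFV against a control database, PAF1KG
#' against an optional external set, and [flag_rare()].
#'
#' @param variants Wide per-variant data frame from [integrate_sample()].
#' @param db A [control_db()].
#' @param external_set Optional external frequency set (see
#'   [compute_external_paf()]).
#' @return `variants` with `pafsu`, `pafdra`, `pafv`, `paf1kg`, `rare`.
#' @export
annotate_population_frequency <- function(variants, db, external_set = NULL) {
  n <- nrow(variants)
  variants$pafsu <- variants$pafdra <- variants$pafv <- variants$paf1kg <-
    rep(NA_real_, n)
  variants$rare <- rep(NA, n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    variants$pafsu[i] <- compute_pafsu(v$su, v$chrom, v$start, v$end,
                                       v$svtype, db)
    if (isTRUE(v$cnv) && v$svtype %in% c("DEL", "DUP")) {
      variants$pafdra[i] <- compute_pafdra(
        v$chrom, v$start, v$end,
        direction = if (v$svtype == "DEL") "loss" else "gain", db)
    }
    q <- list(chrom = v$chrom, start = v$start, end = v$end,
              svtype = v$svtype, cnv = isTRUE(v$cnv))
    variants$pafv[i] <- compute_pafv(q, db)
    if (!is.null(external_set)) {
      variants$paf1kg[i] <- compute_external_paf(q, external_set)
    }
    variants$rare[i] <- flag_rare(variants$pafv[i], variants$pafsu[i],
                                  variants$pafdra[i], variants$paf1kg[i])
  }
  variants
}

#' Attach gene, candidate-gene, pedigree and DGV annotations
#'
#' @param variants Wide per-variant data frame.
#' @param samples Long per-sample table (defines carriers per variant).
#' @param genes Gene table (see [read_gene_models()]).
#' @param disease_terms Optional gene-to-term mapping.
#' @param candidate_genes Optional candidate-gene symbols.
#' @param ped Optional pedigree ([read_ped()]).
#' @param dgv Optional known-variant set for [match_dgv()].
#' @return `variants` with `genes`, `candg`, `ia`, `iua`, `dgv` columns.
#' @export
annotate_variants <- function(variants, samples, genes = NULL,
                              disease_terms = NULL, candidate_genes = NULL,
                              ped = NULL, dgv = NULL) {
  n <- nrow(variants)
  variants$genes <- variants$candg <- variants$dgv <- rep("", n)
  variants$ia <- variants$iua <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    if (!is.null(genes)) {
      g <- annotate_genes(v$chrom, v$start, v$end, genes,
                          disease_terms = disease_terms)
      variants$genes[i] <- paste(g$gene, collapse = ",")
      if (!is.null(candidate_genes)) {
        variants$candg[i] <- candidate_gene_hits(g$gene, candidate_genes)
      }
    }
    if (!is.null(ped)) {
      carriers <- samples$sample_id[samples$id == v$id]
      cc <- pedigree_counts(carriers, ped)
      variants$ia[i] <- cc[["ia"]]
      variants$iua[i] <- cc[["iua"]]
    }
    if (!is.null(dgv)) {
      q <- list(chrom = v$chrom, start = v$start, end = v$end,
                svtype = v$svtype, cnv = isTRUE(v$cnv))
      variants$dgv[i] <- paste(match_dgv(q, dgv), collapse = ",")
    }
  }
  variants
}
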