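# Integration of depth-of-coverage (doc) caller candidates with
# split-read/discordant-pair (srdp) caller candidates.
#
# Candidate calls travel as a pair of data frames:
#   calls:   id, chrom, start, end, svtype (DEL/DUP/INV/BND), caller
#   samples: id, sample_id, sr, dp, su, doc, dra, drf, gt, cnv
# The long per-sample table keeps joint-calling bookkeeping simple and maps
# directly onto the one-row-per-variant-per-sample report.

CALL_COLS <- c("id", "chrom", "start", "end", "svtype", "caller")

#' Construct a candidate call set
#'
#' @param calls Data frame with columns `chrom`, `start`, `end`, `svtype`,
#'   `caller` (an `id` column is added when absent).
#' @param samples Optional per-sample evidence data frame (`id`,
#'   `sample_id`, `sr`, `dp`, plus any DOC columns); `su` is derived.
#' @return List of class `call_set` with elements `calls` and `samples`.
#' @export
call_set <- function(calls, samples = NULL) {
  need_cols(calls, c("chrom", "start", "end", "svtype", "caller"), "calls")
  if (is.null(calls$id)) calls$id <- sprintf("%s_%05d", calls$caller, seq_len(nrow(calls)))
  intra <- calls$svtype != "BND"
  if (any(intra & calls$end < calls$start)) stopf("call with end < start")
  if (is.null(samples)) {
    samples <- data.frame(id = character(), sample_id = character(),
                          sr = integer(), dp = integer(), su = integer(),
                          stringsAsFactors = FALSE)
  }
  if (nrow(samples)) {
    need_cols(samples, c("id", "sample_id"), "sample evidence")
    if (is.null(samples$sr)) samples$sr <- 0L
    if (is.null(samples$dp)) samples$dp <- 0L
    samples$su <- samples$sr + samples$dp
  }
  structure(list(calls = calls[, union(CALL_COLS, names(calls))],
                 samples = samples),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat(sprintf("call_set: %d call(s) [%s], %d sample record(s)\n",
              nrow(x$calls), paste(unique(x$calls$caller), collapse = ","),
              nrow(x$samples)))
  invisible(x)
}

#' Split a call at N-masked regions
#'
#' A call spanning masked intervals is split into the sub-intervals of the
#' call minus the mask; zero-length parts are dropped. Split parts inherit
#' the call's metadata with suffixed ids.
#'
#' @param call One-row data frame (or list) with `chrom`, `start`, `end`.
#' @param mask Data frame of sorted, non-overlapping masked intervals
#'   (`chrom`, `start`, `end`).
#' @return Data frame of one or more calls tiling call minus mask.
#' @export
split_at_masked_regions <- function(call, mask) {
  call <- as.data.frame(call, stringsAsFactors = FALSE)
  m <- mask[mask$chrom == call$chrom, , drop = FALSE]
  if (nrow(m) == 0) return(call)
  kept <- IRanges::setdiff(IRanges::IRanges(call$start, call$end),
                           IRanges::IRanges(m$start, m$end))
  if (length(kept) == 0) return(call[0L, , drop = FALSE])
  if (length(kept) == 1 &&
      IRanges::start(kept) == call$start && IRanges::end(kept) == call$end) {
    return(call)
  }
  out <- call[rep(1L, length(kept)), , drop = FALSE]
  out$start <- IRanges::start(kept)
  out$end <- IRanges::end(kept)
  if (!is.null(out$id)) out$id <- sprintf("%s_p%d", call$id, seq_len(length(kept)))
  rownames(out) <- NULL
  out
}

#' Apply masked-region splitting to every call in a set
#'
#' @param cs A [call_set()].
#' @param mask Masked-region data frame.
#' @return A new `call_set`; per-sample evidence is replicated onto parts.
#' @export
split_calls_at_mask <- function(cs, mask) {
  stopifnot(inherits(cs, "call_set"))
  parts <- do.call(rbind, lapply(seq_len(nrow(cs$calls)), function(i) {
    split_at_masked_regions(cs$calls[i, , drop = FALSE], mask)
  }))
  if (is.null(parts)) parts <- cs$calls[0L, , drop = FALSE]
  # map part ids back to parents to replicate evidence
  parent <- sub("_p[0-9]+$", "", parts$id)
  samples <- cs$samples[cs$samples$id %in% c(parts$id, parent), , drop = FALSE]
  out_samples <- do.call(rbind, lapply(seq_len(nrow(parts)), function(i) {
    sm <- cs$samples[cs$samples$id == parent[i], , drop = FALSE]
    if (nrow(sm)) sm$id <- parts$id[i]
    sm
  }))
  if (is.null(out_samples)) out_samples <- cs$samples[0L, , drop = FALSE]
  call_set(parts, out_samples)
}

#' Breakpoint evidence windows for a CNV call
#'
#' The outer limit (flanking the CNV) is 1% of the CNV length, at least
#' 1 kb and at most 5 kb; the inner limit (towards the CNV center) is half
#' the CNV length, at most 5 kb.
#'
#' @param length CNV length in bases (> 0); vectorized.
#' @return List with numeric `outer` and `inner`.
#' @export
breakpoint_evidence_window <- function(length) {
  stopifnot(all(length > 0))
  list(outer = pmin(pmax(0.01 * length, 1000), 5000),
       inner = pmin(length / 2, 5000))
}

#' Expected read-pair orientation for an SV type
#' @noRd
orientation_matches <- function(svtype, orientation) {
  switch(svtype,
    DEL = orientation == "FR",
    DUP = orientation == "RF",
    INV = orientation %in% c("FF", "RR"),
    rep(TRUE, length(orientation))
  )
}

#' Annotate a DOC call with split-read / discordant-pair evidence
#'
#' Counts DP and SR records whose two mapped ends fall within the
#' breakpoint evidence windows — [start - outer, start + inner] at the 5'
#' breakpoint and the mirrored window at the 3' breakpoint — and whose
#' orientation matches the SV type (DEL: inward FR; DUP: everted RF;
#' INV: same-strand FF/RR).
#'
#' @param call One-row call (list or data frame) with `chrom`, `start`,
#'   `end`, `svtype`.
#' @param dp,sr Evidence data frames ([extract_discordant_pairs()] /
#'   [extract_split_reads()] schema).
#' @param by_sample Return per-sample counts (default) or totals.
#' @return Data frame `sample_id`, `sr`, `dp`, `su` (or one-row totals).
#' @export
annotate_doc_call_with_read_evidence <- function(call, dp, sr,
                                                 by_sample = TRUE) {
  call <- as.list(call)
  win <- breakpoint_evidence_window(call$end - call$start + 1)
  l1 <- call$start - win$outer; l2 <- call$start + win$inner
  r1 <- call$end - win$inner;   r2 <- call$end + win$outer
  hit <- function(ev) {
    if (is.null(ev) || nrow(ev) == 0) return(ev[0L, , drop = FALSE])
    keep <- ev$chrom == call$chrom &
      ev$start >= l1 & ev$start <= l2 &
      ev$end >= r1 & ev$end <= r2 &
      orientation_matches(call$svtype, ev$orientation)
    ev[keep, , drop = FALSE]
  }
  dph <- hit(dp); srh <- hit(sr)
  all_samples <- sort(unique(c(dph$sample_id, srh$sample_id)))
  out <- data.frame(
    sample_id = all_samples,
    sr = vapply(all_samples, function(s) sum(srh$sample_id == s), integer(1)),
    dp = vapply(all_samples, function(s) sum(dph$sample_id == s), integer(1)),
    stringsAsFactors = FALSE
  )
  out$su <- out$sr + out$dp
  rownames(out) <- NULL
  if (!by_sample) {
    out <- data.frame(sr = sum(out$sr), dp = sum(out$dp), su = sum(out$su))
  }
  out
}

#' Gain/loss merge class of an SV type
#' @noRd
merge_class <- function(svtype) {
  c(DEL = "loss", DUP = "gain", INV = "inv", BND = "bnd")[svtype]
}

#' Can two candidate calls be merged?
#'
#' Two calls of the same event class merge when they overlap reciprocally
#' by at least `reciprocal` (default 70%) of each call's length, or when
#' the non-overlapping part of each call is at most `max_residue` bases
#' (default 200).
#'
#' @param a,b One-row calls (list or data frame) with `chrom`, `start`,
#'   `end`, `svtype`.
#' @param reciprocal Reciprocal-overlap threshold.
#' @param max_residue Maximum non-overlapping residue per call, in bases.
#' @return Logical.
#' @export
mergeable <- function(a, b, reciprocal = 0.7, max_residue = 200) {
  a <- as.list(a); b <- as.list(b)
  if (a$chrom != b$chrom) return(FALSE)
  if (merge_class(a$svtype) != merge_class(b$svtype)) return(FALSE)
  if (a$svtype == "BND" || b$svtype == "BND") return(FALSE)
  ov <- iv_overlap(a$start, a$end, b$start, b$end)
  la <- a$end - a$start + 1; lb <- b$end - b$start + 1
  recip <- ov / la >= reciprocal && ov / lb >= reciprocal
  resid <- (la - ov) <= max_residue && (lb - ov) <= max_residue
  recip || resid
}

#' All mergeable pairs among calls (single-linkage edges)
#' @noRd
mergeable_edges <- function(calls, reciprocal = 0.7, max_residue = 200) {
  n <- nrow(calls)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  gr <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$start, calls$end))
  hits <- GenomicRanges::findOverlaps(gr, gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  cand <- cbind(qi[qi < si], si[qi < si])
  # the residue clause can join abutting/disjoint short calls: add near pairs
  near <- GenomicRanges::findOverlaps(gr, gr, maxgap = 200)
  qn <- S4Vectors::queryHits(near); sn <- S4Vectors::subjectHits(near)
  cand <- unique(rbind(cand, cbind(qn[qn < sn], sn[qn < sn])))
  if (nrow(cand) == 0) return(matrix(integer(0), ncol = 2))
  ok <- vapply(seq_len(nrow(cand)), function(k) {
    mergeable(calls[cand[k, 1], ], calls[cand[k, 2], ],
              reciprocal = reciprocal, max_residue = max_residue)
  }, logical(1))
  cand[ok, , drop = FALSE]
}

#' Merge DOC-caller calls across samples
#'
#' Calls of the same event type (gain or loss) that satisfy [mergeable()]
#' are collapsed by single-linkage connected components into one call with
#' the average start and end coordinates; per-sample evidence is retained,
#' taking the maximum of each count per sample across members.
#'
#' @param cs A [call_set()] of doc-caller calls (possibly many samples).
#' @param reciprocal,max_residue Merge-rule parameters, see [mergeable()].
#' @return A merged `call_set`.
#' @export
merge_doc_calls_across_samples <- function(cs, reciprocal = 0.7,
                                           max_residue = 200) {
  stopifnot(inherits(cs, "call_set"))
  calls <- cs$calls
  n <- nrow(calls)
  if (n == 0) return(cs)
  edges <- mergeable_edges(calls, reciprocal, max_residue)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  merged <- lapply(sort(unique(comp)), function(cc) {
    idx <- which(comp == cc)
    mem <- calls[idx, , drop = FALSE]
    out <- mem[1L, , drop = FALSE]
    out$start <- as.integer(round(mean(mem$start)))
    out$end <- as.integer(round(mean(mem$end)))
    out$id <- mem$id[which.min(mem$start)]
    sm <- cs$samples[cs$samples$id %in% mem$id, , drop = FALSE]
    if (nrow(sm)) {
      sm <- merge_sample_evidence(sm, out$id)
    }
    list(call = out, samples = sm)
  })
  calls_out <- do.call(rbind, lapply(merged, `[[`, "call"))
  samples_out <- do.call(rbind, lapply(merged, `[[`, "samples"))
  if (is.null(samples_out)) samples_out <- cs$samples[0L, , drop = FALSE]
  ord <- order(calls_out$chrom, calls_out$start)
  call_set(calls_out[ord, , drop = FALSE], samples_out)
}

#' Collapse per-sample evidence rows: max of counts, mean of DOC metrics
#' @noRd
merge_sample_evidence <- function(sm, new_id) {
  parts <- split(sm, sm$sample_id)
  out <- do.call(rbind, lapply(parts, function(p) {
    r <- p[1L, , drop = FALSE]
    for (cl in intersect(c("sr", "dp", "su"), names(p))) r[[cl]] <- max(p[[cl]])
    for (cl in intersect(c("doc", "dra", "drf", "avg_mq"), names(p))) {
      r[[cl]] <- mean(p[[cl]], na.rm = TRUE)
    }
    r
  }))
  out$id <- new_id
  rownames(out) <- NULL
  out
}

#' Merge DOC-caller calls into SRDP-caller calls
#'
#' Pairs of calls (one per caller) satisfying [mergeable()] fuse into one
#' integrated variant that keeps the more precise srdp coordinates and the
#' union of evidence (per-sample maxima of counts, doc metrics from the
#' doc member when the srdp member lacks them). When one srdp call matches
#' several doc calls (or vice versa) the pair with the highest reciprocal
#' overlap wins and the remainder pass through unmatched; ties break toward
#' the smaller start coordinate. Unmatched calls pass through unchanged.
#'
#' @param doc_cs,srdp_cs [call_set()] objects from the two callers.
#' @param reciprocal,max_residue Merge-rule parameters.
#' @return A `call_set` of integrated variants; the `caller` field is
#'   `"doc,srdp"` for fused records.
#' @export
merge_doc_with_srdp <- function(doc_cs, srdp_cs, reciprocal = 0.7,
                                max_residue = 200) {
  stopifnot(inherits(doc_cs, "call_set"), inherits(srdp_cs, "call_set"))
  dc <- doc_cs$calls; sc <- srdp_cs$calls
  pairs <- NULL
  if (nrow(dc) && nrow(sc)) {
    # prefilter to pairs within merge reach of each other
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(dc$chrom, IRanges::IRanges(dc$start, dc$end)),
      GenomicRanges::GRanges(sc$chrom, IRanges::IRanges(sc$start, sc$end)),
      maxgap = max_residue)
    cand <- data.frame(di = S4Vectors::queryHits(hits),
                       si = S4Vectors::subjectHits(hits))
    ok <- vapply(seq_len(nrow(cand)), function(k) {
      mergeable(dc[cand$di[k], ], sc[cand$si[k], ],
                reciprocal = reciprocal, max_residue = max_residue)
    }, logical(1))
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand)) {
      score <- vapply(seq_len(nrow(cand)), function(k) {
        a <- dc[cand$di[k], ]; b <- sc[cand$si[k], ]
        ov <- iv_overlap(a$start, a$end, b$start, b$end)
        min(ov / (a$end - a$start + 1), ov / (b$end - b$start + 1))
      }, numeric(1))
      ord <- order(-score, pmin(dc$start[cand$di], sc$start[cand$si]),
                   dc$start[cand$di], sc$start[cand$si])
      cand <- cand[ord, , drop = FALSE]
      used_d <- logical(nrow(dc)); used_s <- logical(nrow(sc))
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        if (!used_d[cand$di[k]] && !used_s[cand$si[k]]) {
          keep[k] <- TRUE
          used_d[cand$di[k]] <- TRUE
          used_s[cand$si[k]] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  fused_calls <- NULL; fused_samples <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    fused <- lapply(seq_len(nrow(pairs)), function(k) {
      d <- dc[pairs$di[k], , drop = FALSE]
      s <- sc[pairs$si[k], , drop = FALSE]
      out <- s
      out$caller <- "doc,srdp"
      out$id <- paste0("iv_", s$id)
      sm <- rbind_fill(doc_cs$samples[doc_cs$samples$id == d$id, , drop = FALSE],
                       srdp_cs$samples[srdp_cs$samples$id == s$id, , drop = FALSE])
      if (!is.null(sm) && nrow(sm)) sm <- merge_sample_evidence(sm, out$id)
      list(call = out, samples = sm)
    })
    fused_calls <- do.call(rbind, lapply(fused, `[[`, "call"))
    fused_samples <- do.call(rbind_fill, lapply(fused, `[[`, "samples"))
  }
  d_keep <- if (is.null(pairs)) seq_len(nrow(dc)) else setdiff(seq_len(nrow(dc)), pairs$di)
  s_keep <- if (is.null(pairs)) seq_len(nrow(sc)) else setdiff(seq_len(nrow(sc)), pairs$si)
  calls_out <- rbind_fill(fused_calls, dc[d_keep, , drop = FALSE],
                          sc[s_keep, , drop = FALSE])
  samples_out <- rbind_fill(
    fused_samples,
    doc_cs$samples[doc_cs$samples$id %in% dc$id[d_keep], , drop = FALSE],
    srdp_cs$samples[srdp_cs$samples$id %in% sc$id[s_keep], , drop = FALSE])
  if (is.null(samples_out)) samples_out <- doc_cs$samples[0L, , drop = FALSE]
  ord <- order(calls_out$chrom, calls_out$start)
  call_set(calls_out[ord, , drop = FALSE], samples_out)
}

#' rbind data frames with differing columns, filling with NA
#' @noRd
rbind_fill <- function(...) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (length(dfs) == 0) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[, cols, drop = FALSE]
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  out
}

#' Split a joint call with mixed DOC support
#'
#' In a joint-called batch, when some carrier samples show a depth change
#' (CNV state) and others carry only split-read/discordant-pair evidence,
#' the variant is emitted twice: one CNV call restricted to the
#' DOC-supported samples and one copy-neutral (CNV = 0) call for the rest.
#'
#' @param call One-row call data frame.
#' @param samples Per-sample evidence rows for this call, carrying `dra`
#'   and `drf` (used via [flag_cnv()]) and read counts.
#' @return List of 1 or 2 elements, each `list(call=, samples=, cnv=)`.
#' @export
split_mixed_support <- function(call, samples) {
  cnv_state <- vapply(seq_len(nrow(samples)), function(i) {
    dra <- samples$dra[i]
    drf <- if (!is.null(samples$drf)) samples$drf[i] else NA_real_
    if (!is.finite(dra)) return(FALSE)
    flag_cnv(dra, drf)
  }, logical(1))
  su <- if (is.null(samples$su)) rep(0L, nrow(samples)) else
    ifelse(is.na(samples$su), 0L, samples$su)
  read_only <- !cnv_state & su > 0
  if (call$svtype %in% c("DEL", "DUP") && any(cnv_state) && any(read_only)) {
    a <- call; a$id <- paste0(call$id, "_cnv")
    b <- call; b$id <- paste0(call$id, "_neutral")
    sa <- samples[cnv_state, , drop = FALSE]; sa$id <- a$id
    sb <- samples[read_only, , drop = FALSE]; sb$id <- b$id
    return(list(list(call = a, samples = sa, cnv = TRUE),
                list(call = b, samples = sb, cnv = FALSE)))
  }
  list(list(call = call, samples = samples, cnv = any(cnv_state)))
}
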