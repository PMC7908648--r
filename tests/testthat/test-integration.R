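mkcall <- function(start, end, svtype = "DEL", chrom = "ctg1",
                   caller = "doc", id = "c1") {
  data.frame(id = id, chrom = chrom, start = start, end = end,
             svtype = svtype, caller = caller, stringsAsFactors = FALSE)
}

test_that("masked-region splitting excises the masked part", {
  mask <- data.frame(chrom = "ctg1", start = 400, end = 599)
  out <- split_at_masked_regions(mkcall(100, 899), mask)
  expect_equal(out$start, c(100, 600))
  expect_equal(out$end, c(399, 899))

  # disjoint mask leaves the call unchanged
  out2 <- split_at_masked_regions(mkcall(100, 300), mask)
  expect_equal(out2$start, 100)
  expect_equal(out2$end, 300)

  # fully masked call vanishes
  out3 <- split_at_masked_regions(mkcall(450, 550), mask)
  expect_equal(nrow(out3), 0)

  # random call/mask pairs against the per-base oracle
  set.seed(21)
  for (i in 1:50) {
    s <- sample.int(5000, 1); e <- s + sample.int(3000, 1)
    ms <- sort(sample.int(8000, 3))
    mask_df <- data.frame(chrom = "ctg1", start = ms,
                          end = ms + sample.int(500, 3))
    mask_df <- as.data.frame(IRanges::reduce(
      IRanges::IRanges(mask_df$start, mask_df$end)))[, 1:2]
    names(mask_df) <- c("start", "end"); mask_df$chrom <- "ctg1"
    got <- split_at_masked_regions(mkcall(s, e), mask_df)
    want <- oracle_interval_minus_mask(s, e, mask_df$start, mask_df$end)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("breakpoint evidence windows follow the clamped formulas", {
  w <- breakpoint_evidence_window(50000)
  expect_equal(w$outer, 1000)   # 1% of 50 kb = 500, clamped up to 1 kb
  expect_equal(w$inner, 5000)   # half of 50 kb, capped at 5 kb
  w2 <- breakpoint_evidence_window(1e6)
  expect_equal(w2$outer, 5000)  # 1% of 1 Mb = 10 kb, capped at 5 kb
  expect_equal(w2$inner, 5000)
  w3 <- breakpoint_evidence_window(2000)
  expect_equal(w3$outer, 1000)
  expect_equal(w3$inner, 1000)
})

test_that("read-evidence annotation respects windows and orientation", {
  call <- mkcall(10000, 20000, "DEL")
  dp_in <- data.frame(chrom = "ctg1", start = 10000 - (1:5) * 50,
                      end = 20000 + (1:5) * 50, mate_chrom = "ctg1",
                      orientation = "FR", mapq = 60, sample_id = "S1",
                      stringsAsFactors = FALSE)
  cnt <- annotate_doc_call_with_read_evidence(call, dp_in, NULL)
  expect_equal(cnt$dp, 5)

  # same positions but everted orientation: not deletion-like
  dp_ev <- transform(dp_in, orientation = "RF")
  cnt2 <- annotate_doc_call_with_read_evidence(call, dp_ev, NULL)
  expect_equal(nrow(cnt2), 0)

  # everted pairs do support a duplication
  cnt3 <- annotate_doc_call_with_read_evidence(
    mkcall(10000, 20000, "DUP"), dp_ev, NULL)
  expect_equal(cnt3$dp, 5)

  # brute-force window + orientation oracle on a simulated deletion
  vars <- data.frame(chrom = "ctg1", start = 50001, end = 60000,
                     svtype = "DEL", genotype = "0/1",
                     stringsAsFactors = FALSE)
  es <- simulate_sample(sim_config(c(ctg1 = 2e5), vars, seed = 4))
  got <- annotate_doc_call_with_read_evidence(
    mkcall(50001, 60000, "DEL"), es$dp, es$sr)
  w <- breakpoint_evidence_window(10000)
  in_win <- function(ev) {
    sum(ev$orientation == "FR" &
          ev$start >= 50001 - w$outer & ev$start <= 50001 + w$inner &
          ev$end >= 60000 - w$inner & ev$end <= 60000 + w$outer)
  }
  expect_equal(got$dp, in_win(es$dp))
  expect_equal(got$sr, in_win(es$sr))
})

test_that("mergeable implements reciprocal-overlap-or-residue and is symmetric", {
  a <- mkcall(1, 1000); b <- mkcall(151, 1150)
  expect_true(mergeable(a, b))     # 85% reciprocal
  c_ <- mkcall(901, 5000)
  expect_false(mergeable(a, c_))   # 10%/2.4%, residues 900/4100
  d <- mkcall(1, 10000); e <- mkcall(151, 10100)
  expect_true(mergeable(d, e))     # ~98.5% reciprocal and small residues
  expect_false(mergeable(a, mkcall(151, 1150, "DUP")))  # class mismatch

  set.seed(31)
  for (i in 1:200) {
    s1 <- sample.int(10000, 1); e1 <- s1 + sample.int(3000, 1)
    s2 <- sample.int(10000, 1); e2 <- s2 + sample.int(3000, 1)
    x <- mkcall(s1, e1); y <- mkcall(s2, e2)
    expect_equal(mergeable(x, y), oracle_mergeable(s1, e1, s2, e2))
    expect_equal(mergeable(x, y), mergeable(y, x))
  }
})

test_that("cross-sample merging collapses connected components", {
  # identical call in 3 samples
  calls <- do.call(rbind, lapply(1:3, function(i) {
    mkcall(1000, 3000, id = paste0("c", i))
  }))
  sm <- data.frame(id = paste0("c", 1:3), sample_id = paste0("S", 1:3),
                   sr = 1:3, dp = 0L, stringsAsFactors = FALSE)
  merged <- merge_doc_calls_across_samples(call_set(calls, sm))
  expect_equal(nrow(merged$calls), 1)
  expect_equal(nrow(merged$samples), 3)
  expect_equal(merged$calls$start, 1000)

  # two non-mergeable calls stay apart
  calls2 <- rbind(mkcall(1000, 3000, id = "a"), mkcall(50000, 60000, id = "b"))
  merged2 <- merge_doc_calls_across_samples(call_set(calls2))
  expect_equal(nrow(merged2$calls), 2)

  # merged coordinates are the member averages
  calls3 <- rbind(mkcall(1000, 3000, id = "a"), mkcall(1100, 3100, id = "b"))
  merged3 <- merge_doc_calls_across_samples(call_set(calls3))
  expect_equal(merged3$calls$start, 1050)
  expect_equal(merged3$calls$end, 3050)

  # random clusters: component structure equals brute-force closure
  set.seed(41)
  for (rep in 1:10) {
    n <- 12
    anchors <- sample.int(50000, 4)
    st <- anchors[sample.int(4, n, replace = TRUE)] + sample.int(300, n)
    calls_r <- data.frame(id = paste0("r", 1:n), chrom = "ctg1", start = st,
                          end = st + 2000 + sample.int(300, n),
                          svtype = sample(c("DEL", "DUP"), n, TRUE),
                          caller = "doc", stringsAsFactors = FALSE)
    merged_r <- merge_doc_calls_across_samples(call_set(calls_r))
    want_n <- length(unique(oracle_components(calls_r)))
    expect_equal(nrow(merged_r$calls), want_n)
  }
})

test_that("merging is idempotent", {
  set.seed(43)
  st <- sample.int(50000, 10)
  calls <- data.frame(id = paste0("r", 1:10), chrom = "ctg1", start = st,
                      end = st + 1000, svtype = "DEL", caller = "doc",
                      stringsAsFactors = FALSE)
  m1 <- merge_doc_calls_across_samples(call_set(calls))
  m2 <- merge_doc_calls_across_samples(m1)
  expect_equal(m2$calls[, c("chrom", "start", "end", "svtype")],
               m1$calls[, c("chrom", "start", "end", "svtype")])
})

test_that("doc calls fuse into srdp calls keeping srdp coordinates", {
  doc <- call_set(mkcall(10000, 20050, id = "d1"),
                  data.frame(id = "d1", sample_id = "S1", sr = 0L, dp = 0L,
                             dra = 0.5, stringsAsFactors = FALSE))
  srdp <- call_set(mkcall(10012, 20001, caller = "srdp", id = "s1"),
                   data.frame(id = "s1", sample_id = "S1", sr = 4L, dp = 6L,
                              stringsAsFactors = FALSE))
  merged <- merge_doc_with_srdp(doc, srdp)
  expect_equal(nrow(merged$calls), 1)
  expect_equal(merged$calls$start, 10012)
  expect_equal(merged$calls$end, 20001)
  expect_equal(merged$calls$caller, "doc,srdp")
  expect_equal(merged$samples$su, 10L)
  expect_equal(merged$samples$dra, 0.5)

  # doc-only call passes through unchanged
  doc2 <- call_set(rbind(mkcall(10000, 20050, id = "d1"),
                         mkcall(100000, 101000, id = "d2")))
  merged2 <- merge_doc_with_srdp(doc2, srdp)
  expect_equal(nrow(merged2$calls), 2)
  expect_true(any(merged2$calls$caller == "doc"))

  # best reciprocal overlap wins when one srdp call matches two doc calls
  doc3 <- call_set(rbind(mkcall(10000, 20000, id = "near"),
                         mkcall(9000, 21000, id = "far")))
  srdp3 <- call_set(mkcall(10001, 20001, caller = "srdp", id = "s1"))
  merged3 <- merge_doc_with_srdp(doc3, srdp3)
  fused <- merged3$calls[merged3$calls$caller == "doc,srdp", ]
  expect_equal(nrow(fused), 1)
  expect_equal(fused$start, 10001)
  expect_true("far" %in% merged3$calls$id)
})

test_that("mixed DOC support splits joint calls into CNV and copy-neutral", {
  call <- mkcall(1000, 5000, id = "j1")
  both_cnv <- data.frame(id = "j1", sample_id = c("A", "B"), sr = 2L,
                         dp = 2L, su = 4L, dra = c(0.5, 0.5),
                         stringsAsFactors = FALSE)
  expect_length(split_mixed_support(call, both_cnv), 1)

  mixed <- data.frame(id = "j1", sample_id = c("A", "B"), sr = c(2L, 4L),
                      dp = c(2L, 4L), su = c(4L, 8L), dra = c(0.5, 1.0),
                      stringsAsFactors = FALSE)
  out <- split_mixed_support(call, mixed)
  expect_length(out, 2)
  expect_true(out[[1]]$cnv)
  expect_false(out[[2]]$cnv)
  expect_equal(out[[1]]$samples$sample_id, "A")
  expect_equal(out[[2]]$samples$sample_id, "B")

  neutral <- transform(both_cnv, dra = 1.0)
  out3 <- split_mixed_support(call, neutral)
  expect_length(out3, 1)
  expect_false(out3[[1]]$cnv)
})

test_that("no integrated variant overlaps the mask after splitting", {
  set.seed(47)
  st <- seq(1000, 91000, by = 10000)
  calls <- data.frame(id = paste0("c", seq_along(st)), chrom = "ctg1",
                      start = st, end = st + 6000, svtype = "DEL",
                      caller = "doc", stringsAsFactors = FALSE)
  mask <- data.frame(chrom = "ctg1", start = c(5000, 45000),
                     end = c(12000, 52000))
  out <- split_calls_at_mask(call_set(calls), mask)
  for (i in seq_len(nrow(out$calls))) {
    for (j in seq_len(nrow(mask))) {
      ov <- min(out$calls$end[i], mask$end[j]) -
        max(out$calls$start[i], mask$start[j]) + 1
      expect_lte(ov, 0)
    }
  }
})
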