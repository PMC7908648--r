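# Shared fixture builders. Everything is generated in code; no binary
# fixtures on disk.

# flat coverage track: `depth`x everywhere, MQ `mq`, one or more contigs
flat_track <- function(contig_lengths = c(ctg1 = 1e6), depth = 30, mq = 60,
                       bin_size = 100L) {
  d <- lapply(contig_lengths, function(len) rep(depth, ceiling(len / bin_size)))
  q <- lapply(contig_lengths, function(len) rep(mq, ceiling(len / bin_size)))
  coverage_track(d, q, bin_size = bin_size, contig_lengths = contig_lengths)
}

toy_contig_table <- function(contig_lengths = c(ctg1 = 1e6),
                             classes = NULL) {
  data.frame(contig = names(contig_lengths),
             length = as.numeric(contig_lengths),
             class = classes %||% rep("autosome", length(contig_lengths)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force insert-cutoff oracle: walk sorted distances accumulating the
# count until it reaches the threshold density
oracle_upper_cutoff <- function(distances, region_mb, pairs_per_mb = 100) {
  srt <- sort(distances, decreasing = TRUE)
  cum <- 0
  for (d in srt) {
    cum <- cum + 1
    if (cum / region_mb >= pairs_per_mb) return(d)
  }
  NA_real_
}
oracle_lower_cutoff <- function(distances, region_mb, pairs_per_mb = 100) {
  srt <- sort(distances)
  cum <- 0
  for (d in srt) {
    cum <- cum + 1
    if (cum / region_mb >= pairs_per_mb) return(d)
  }
  NA_real_
}

# brute-force per-base oracle for interval subtraction
oracle_interval_minus_mask <- function(start, end, mask_start, mask_end) {
  pos <- start:end
  keep <- rep(TRUE, length(pos))
  for (i in seq_along(mask_start)) {
    keep[pos >= mask_start[i] & pos <= mask_end[i]] <- FALSE
  }
  if (!any(keep)) return(data.frame(start = integer(), end = integer()))
  r <- rle(keep)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  data.frame(start = pos[starts[idx]], end = pos[ends[idx]])
}

# literal restatement of the merge rule, for oracle comparison
oracle_mergeable <- function(s1, e1, s2, e2, reciprocal = 0.7,
                             max_residue = 200) {
  ov <- max(0, min(e1, e2) - max(s1, s2) + 1)
  l1 <- e1 - s1 + 1; l2 <- e2 - s2 + 1
  (ov / l1 >= reciprocal && ov / l2 >= reciprocal) ||
    ((l1 - ov) <= max_residue && (l2 - ov) <= max_residue)
}

# transitive closure of the mergeable relation by repeated expansion
oracle_components <- function(calls, reciprocal = 0.7, max_residue = 200) {
  n <- nrow(calls)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          calls$chrom[i] == calls$chrom[j] &&
          calls$svtype[i] == calls$svtype[j] &&
          oracle_mergeable(calls$start[i], calls$end[i],
                           calls$start[j], calls$end[j],
                           reciprocal, max_residue)) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# all-pairs brute-force variant matcher (re-states the matching rules)
oracle_match_variant <- function(q, r, tol = 1000) {
  if (q$chrom != r$chrom || q$svtype != r$svtype || q$cnv != r$cnv) return(FALSE)
  if (!q$cnv) {
    return(abs(q$start - r$start) <= tol && abs(q$end - r$end) <= tol)
  }
  ov <- max(0, min(q$end, r$end) - max(q$start, r$start) + 1)
  qlen <- q$end - q$start + 1; rlen <- r$end - r$start + 1
  if (ov < 0.2 * rlen) return(FALSE)
  if (qlen < 1000) ov >= 0.7 * qlen else ov >= 0.9 * qlen
}

random_variant_set <- function(n, chrom = "ctg1", max_pos = 1e6,
                               types = c("DEL", "DUP", "INV")) {
  start <- sample.int(max_pos, n)
  len <- sample.int(20000, n) + 50
  svtype <- sample(types, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + len - 1,
             svtype = svtype, cnv = svtype %in% c("DEL", "DUP"),
             stringsAsFactors = FALSE)
}
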