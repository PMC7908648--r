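test_that("genome baseline estimation handles autosomes and sex chromosomes", {
  lens <- c(a1 = 2e5, a2 = 2e5, chrX = 2e5, chrY = 2e5)
  ct <- toy_contig_table(lens, classes = c("autosome", "autosome", "X", "Y"))

  # uniform 30x everywhere: XX-like genome
  tr <- flat_track(lens, depth = 30)
  ge <- estimate_genome_coverage(tr, ct)
  expect_equal(ge$autosomal, 30)
  expect_equal(ge$x$ratio, 1.0)

  # XY male: 15x on both sex chromosomes
  tr2 <- coverage_track(
    list(a1 = rep(30, 2000), a2 = rep(30, 2000),
         chrX = rep(15, 2000), chrY = rep(15, 2000)),
    bin_size = 100L, contig_lengths = lens)
  ge2 <- estimate_genome_coverage(tr2, ct)
  expect_equal(ge2$x$ratio, 0.5)
  expect_equal(ge2$y$ratio, 0.5)

  # rounding in fractions of 0.5: X at 0.53x autosomal rounds to 0.5;
  # nearest-multiple oracle round(2 * x) / 2
  tr3 <- coverage_track(
    list(a1 = rep(30, 2000), a2 = rep(30, 2000),
         chrX = rep(30 * 0.53, 2000), chrY = rep(0, 2000)),
    bin_size = 100L, contig_lengths = lens)
  ge3 <- estimate_genome_coverage(tr3, ct)
  expect_equal(ge3$x$ratio, round(2 * 0.53) / 2)
  expect_equal(ge3$x$ratio, 0.5)

  expect_error(
    estimate_genome_coverage(flat_track(c(chrX = 1e5)),
                             toy_contig_table(c(chrX = 1e5), "X")),
    "autosome")
})

test_that("baseline is median-robust to one aberrant autosome window", {
  lens <- setNames(rep(2e5, 5), paste0("a", 1:5))
  ct <- toy_contig_table(lens)
  depth <- lapply(lens, function(l) rep(30, 2000))
  depth$a3 <- rep(60, 2000)  # whole-chromosome duplication-like shift
  tr <- coverage_track(depth, bin_size = 100L, contig_lengths = lens)
  ge <- estimate_genome_coverage(tr, ct)
  expect_equal(ge$autosomal, 30)
})

test_that("DOC metrics implement DRA, DRF and the MQ one-third rule", {
  # forced arithmetic: variant at 15x, flanks and genome at 30x
  d <- rep(30, 3000); d[1001:2000] <- 15
  tr <- coverage_track(list(ctg1 = d), bin_size = 100L)
  ge <- estimate_genome_coverage(tr, toy_contig_table(c(ctg1 = 3e5)),
                                 autosome_window = c(200001, 300000))
  m <- compute_doc_metrics("ctg1", 100001, 200000, tr, ge)
  expect_equal(m$dra, 0.5)
  expect_equal(m$drf, 0.5)
  expect_true(m$mq_restricted)

  # only 10% of bins reach MQ >= 50: restriction dropped
  mq <- rep(60, 3000); mq[1001:1900] <- 20
  tr2 <- coverage_track(list(ctg1 = d), list(ctg1 = mq), bin_size = 100L)
  m2 <- compute_doc_metrics("ctg1", 100001, 200000, tr2, ge)
  expect_false(m2$mq_restricted)
  expect_equal(m2$dra, 0.5)

  # majority of the variant above MQ 50: restriction applies, low-MQ bins
  # excluded from the mean
  d3 <- rep(30, 3000); d3[1001:1200] <- 300
  mq3 <- rep(60, 3000); mq3[1001:1200] <- 20
  tr3 <- coverage_track(list(ctg1 = d3), list(ctg1 = mq3), bin_size = 100L)
  m3 <- compute_doc_metrics("ctg1", 100001, 200000, tr3, ge)
  expect_true(m3$mq_restricted)
  expect_equal(m3$doc, 30)

  # random tracks: DRA equals the per-base mean ratio oracle
  set.seed(7)
  for (i in 1:20) {
    dd <- rpois(1000, 30)
    trr <- coverage_track(list(ctg1 = dd), bin_size = 100L)
    ger <- estimate_genome_coverage(trr, toy_contig_table(c(ctg1 = 1e5)),
                                    autosome_window = c(1, 1e5))
    s <- sample.int(9e4, 1); e <- s + sample.int(9999, 1)
    per_base <- rep(dd, each = 100)[s:e]
    mm <- compute_doc_metrics("ctg1", s, e, trr, ger)
    expect_equal(mm$dra, mean(per_base) / ger$autosomal, tolerance = 1e-12)
  }
})

test_that("DRF falls back to a single flank at contig edges", {
  d <- rep(30, 1000); d[1:100] <- 15
  tr <- coverage_track(list(ctg1 = d), bin_size = 100L)
  ge <- estimate_genome_coverage(tr, toy_contig_table(c(ctg1 = 1e5)),
                                 autosome_window = c(20001, 1e5))
  m <- compute_doc_metrics("ctg1", 1, 10000, tr, ge)
  expect_equal(m$drf, 0.5)  # right flank only
})

test_that("CNV flag and genotype bins partition the DRA axis", {
  expect_false(flag_cnv(1.0, 1.0))
  expect_true(flag_cnv(0.79))
  expect_true(flag_cnv(1.0, 1.21))  # DRA or DRF
  expect_false(flag_cnv(0.8, 1.2))  # boundaries are copy-neutral

  expect_equal(assign_genotype(0.5), "0/1")
  expect_equal(assign_genotype(0.1), "1/1")
  expect_equal(assign_genotype(1.9), "1/1")
  expect_equal(assign_genotype(c(0.2, 0.8, 1.2, 1.75)),
               c("0/1", "./.", "./.", "0/1"))

  # dense-grid partition: every DRA gets exactly one genotype and the
  # copy-neutral genotype coincides with the unflagged band
  grid <- seq(0, 3, by = 0.001)
  gt <- assign_genotype(grid)
  expect_true(all(gt %in% c("0/1", "1/1", "./.")))
  flags <- vapply(grid, flag_cnv, logical(1))
  expect_equal(gt == "./.", !flags)
})

test_that("copy-number point estimate scales DRA by ploidy", {
  expect_equal(copy_number_estimate(0.5, 2), 1L)
  expect_equal(copy_number_estimate(1.0, 1), 1L)
  expect_equal(copy_number_estimate(2.05, 2), 4L)
})

test_that("population coverage SD is the population SD across samples", {
  m <- matrix(1, nrow = 4, ncol = 10)
  expect_equal(population_coverage_sd(m), rep(0, 10))
  m2 <- rbind(rep(0.9, 3), rep(1.1, 3))
  expect_equal(population_coverage_sd(m2), rep(0.1, 3))
  # sampling oracle: per-interval noise sigma = 0.1
  set.seed(9)
  m3 <- matrix(rnorm(200 * 500, 1, 0.1), nrow = 200)
  expect_equal(mean(population_coverage_sd(m3)), 0.1, tolerance = 0.1)
})

test_that("homozygous deletions are recovered as 1/1 in nearly all simulations", {
  vars <- data.frame(chrom = "ctg1", start = 100001, end = 105000,
                     svtype = "DEL", genotype = "1/1",
                     stringsAsFactors = FALSE)
  ct <- toy_contig_table(c(ctg1 = 4e5))
  hits <- vapply(1:60, function(s) {
    es <- simulate_sample(sim_config(c(ctg1 = 4e5), vars, seed = s))
    ge <- estimate_genome_coverage(es$track, ct,
                                   autosome_window = c(150001, 400000))
    m <- compute_doc_metrics("ctg1", 100001, 105000, es$track, ge)
    m$dra < 0.2 && assign_genotype(m$dra) == "1/1"
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("coverage tracks round-trip through fixed-step wiggle", {
  tr <- flat_track(c(ctg1 = 5e4), depth = 12, mq = 55)
  tr$contigs$ctg1$depth[10:20] <- 99
  f <- withr::local_tempfile(fileext = ".wig")
  write_coverage_wig(tr, f)
  tr2 <- read_coverage_wig(f, contig_lengths = c(ctg1 = 5e4))
  expect_equal(tr2$bin_size, tr$bin_size)
  expect_equal(tr2$contigs$ctg1$depth, tr$contigs$ctg1$depth)
  expect_equal(tr2$contigs$ctg1$mq, tr$contigs$ctg1$mq)
})
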