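brkp_rows <- function(chrom, positions, orientation, count) {
  data.frame(chrom = chrom, pos = positions, orientation = orientation,
             count = count, sample_count = count, stringsAsFactors = FALSE)
}

test_that("PAFSU follows SUC / SU / NCS with oriented breakpoint windows", {
  # 200 matching control reads across 500 samples against SU = 10 -> 4%
  db <- control_db(500,
                   sr_brkp = brkp_rows("ctg1", c(10000, 20000), "FR", 50),
                   dp_brkp = brkp_rows("ctg1", c(10100, 19900), "FR", 50))
  paf <- compute_pafsu(10, "ctg1", 10000, 20000, "DEL", db)
  expect_equal(paf, 0.04)

  # wrong orientation contributes nothing
  db2 <- control_db(500, dp_brkp = brkp_rows("ctg1", c(10000, 20000), "RF", 100))
  expect_equal(compute_pafsu(10, "ctg1", 10000, 20000, "DEL", db2), 0)
  # but supports a duplication
  expect_equal(compute_pafsu(10, "ctg1", 10000, 20000, "DUP", db2),
               200 / 10 / 500)

  # outside the 1000-base flank contributes nothing
  db3 <- control_db(500, dp_brkp = brkp_rows("ctg1", 15000, "FR", 100))
  expect_equal(compute_pafsu(10, "ctg1", 10000, 20000, "DEL", db3), 0)

  # undefined for SU = 0
  expect_true(is.na(compute_pafsu(0, "ctg1", 1, 2, "DEL", db)))
})

test_that("PAFDRA counts samples concordant over >= 90% of the CNV", {
  # 50 of 500 controls deleted over the full CNV -> 0.1
  n <- 500
  m <- matrix(1, nrow = n, ncol = 30)
  m[1:50, 11:20] <- 0.5
  db <- control_db(n, dra_1kb = list(ctg1 = m))
  expect_equal(compute_pafdra("ctg1", 10001, 20000, "loss", db), 0.1)
  expect_equal(compute_pafdra("ctg1", 10001, 20000, "gain", db), 0)

  # a sample concordant over only 80% of intervals does not count
  m2 <- matrix(1, nrow = 10, ncol = 10)
  m2[1, 1:8] <- 0.5
  m2[2, 1:9] <- 0.5
  db2 <- control_db(10, dra_1kb = list(ctg1 = m2))
  expect_equal(compute_pafdra("ctg1", 1, 10000, "loss", db2), 0.1)

  # sub-kilobase CNV uses its single overlapping interval
  m3 <- matrix(1, nrow = 4, ncol = 5); m3[3, 2] <- 1.6
  db3 <- control_db(4, dra_1kb = list(ctg1 = m3))
  expect_equal(compute_pafdra("ctg1", 1200, 1500, "gain", db3), 0.25)
})

test_that("variant matching applies the breakpoint and overlap clauses", {
  q <- list(chrom = "ctg1", start = 1, end = 10000, svtype = "DEL", cnv = TRUE)
  expect_true(match_variant(q, q))

  # overlap is 100% of query but only 10% of reference -> no match
  r <- list(chrom = "ctg1", start = 1, end = 100000, svtype = "DEL", cnv = TRUE)
  expect_false(match_variant(q, r))

  # 800-bp query with 75% overlap matches under the <1-kb clause
  q2 <- list(chrom = "ctg1", start = 1, end = 800, svtype = "DEL", cnv = TRUE)
  r2 <- list(chrom = "ctg1", start = 201, end = 1400, svtype = "DEL", cnv = TRUE)
  expect_true(match_variant(q2, r2))
  # ...whereas a 1.2-kb query with 75% overlap fails the 90% clause
  q3 <- list(chrom = "ctg1", start = 1, end = 1200, svtype = "DEL", cnv = TRUE)
  r3 <- list(chrom = "ctg1", start = 301, end = 1800, svtype = "DEL", cnv = TRUE)
  expect_false(match_variant(q3, r3))

  # copy-neutral: breakpoint deviation up to 1000 bases
  qn <- list(chrom = "ctg1", start = 5000, end = 50000, svtype = "INV", cnv = FALSE)
  rn <- list(chrom = "ctg1", start = 5900, end = 50900, svtype = "INV", cnv = FALSE)
  expect_true(match_variant(qn, rn))
  rn2 <- list(chrom = "ctg1", start = 6100, end = 50000, svtype = "INV", cnv = FALSE)
  expect_false(match_variant(qn, rn2))

  # CNV state must agree
  qx <- list(chrom = "ctg1", start = 1, end = 10000, svtype = "DEL", cnv = FALSE)
  expect_false(match_variant(qx, q))

  # brute-force all-pairs oracle on random sets
  set.seed(71)
  for (i in 1:30) {
    qs <- random_variant_set(6)
    rs <- random_variant_set(6)
    for (a in seq_len(6)) for (b in seq_len(6)) {
      expect_equal(match_variant(qs[a, ], rs[b, ]),
                   oracle_match_variant(qs[a, ], rs[b, ]))
    }
  }
})

test_that("PAFV reports the best-matching control variant's carrier fraction", {
  ctrl <- data.frame(chrom = "ctg1", start = c(1000, 5e5), end = c(11000, 6e5),
                     svtype = "DEL", cnv = TRUE, carriers = c(5L, 50L),
                     stringsAsFactors = FALSE)
  db <- control_db(500, variants = ctrl)
  q <- list(chrom = "ctg1", start = 1000, end = 11000, svtype = "DEL", cnv = TRUE)
  expect_equal(compute_pafv(q, db), 0.01)
  q2 <- list(chrom = "ctg1", start = 9e6, end = 9.01e6, svtype = "DEL", cnv = TRUE)
  expect_equal(compute_pafv(q2, db), 0)
})

test_that("external PAF takes the best match's AF field", {
  ref <- data.frame(chrom = "ctg1", start = c(1000, 1100), end = c(11000, 10900),
                    svtype = "DEL", cnv = TRUE, af = c(0.2, 0.35),
                    stringsAsFactors = FALSE)
  q <- list(chrom = "ctg1", start = 1000, end = 11000, svtype = "DEL", cnv = TRUE)
  expect_equal(compute_external_paf(q, ref), 0.2)  # larger overlap wins
  expect_equal(compute_external_paf(
    list(chrom = "ctg1", start = 5e6, end = 5.1e6, svtype = "DEL", cnv = TRUE),
    ref), 0)
})

test_that("the rare flag uses a strict 1% threshold over four PAFs", {
  expect_false(flag_rare(0.005, 0, 0.02, 0))  # any PAF > 0.01 -> common
  expect_true(flag_rare(0, 0, 0, 0))
  expect_true(flag_rare(0.01, 0.01, 0.01, 0.01))  # strictly greater only
  expect_true(flag_rare(NA, NA, NA, NA))  # missing treated as 0
})

test_that("control databases round-trip through the on-disk directory layout", {
  set.seed(73)
  db <- control_db(
    12,
    sr_brkp = brkp_rows("ctg1", sort(sample.int(1e5, 5)), "FR", 3:7),
    dp_brkp = brkp_rows("ctg1", sort(sample.int(1e5, 4)), "RF", 2:5),
    dra_1kb = list(ctg1 = matrix(rnorm(12 * 20, 1, 0.1), nrow = 12)),
    variants = data.frame(chrom = "ctg1", start = 1000L, end = 9000L,
                          svtype = "DEL", cnv = TRUE, carriers = 3L,
                          stringsAsFactors = FALSE))
  dir <- withr::local_tempdir()
  save_control_db(db, dir)
  db2 <- load_control_db(dir)
  expect_equal(db2$n_samples, db$n_samples)
  expect_equal(db2$sr_brkp, db$sr_brkp, ignore_attr = TRUE)
  expect_equal(db2$dp_brkp, db$dp_brkp, ignore_attr = TRUE)
  expect_equal(db2$variants, db$variants, ignore_attr = TRUE)
  expect_equal(unname(db2$dra_1kb$ctg1), unname(db$dra_1kb$ctg1),
               tolerance = 1e-6)
})

test_that("cohort simulation recovers planted carrier fractions", {
  vars <- data.frame(chrom = "ctg1",
                     start = c(10001, 30001, 50001),
                     end = c(14000, 34000, 54000),
                     svtype = "DEL", af = c(0, 0.1, 0.5),
                     stringsAsFactors = FALSE)
  cfg <- sim_config(c(ctg1 = 1e5), vars, seed = 20)
  coh <- simulate_cohort(cfg, n_samples = 200)
  # PAFV equals the realized carrier fraction exactly
  for (i in 1:3) {
    q <- list(chrom = "ctg1", start = vars$start[i], end = vars$end[i],
              svtype = "DEL", cnv = TRUE)
    expect_equal(compute_pafv(q, coh$db), coh$carrier_counts[i] / 200)
  }
  # PAFDRA close to the planted carrier fraction
  pd <- compute_pafdra("ctg1", vars$start[3], vars$end[3], "loss", coh$db)
  expect_equal(pd, coh$carrier_counts[3] / 200, tolerance = 0.05)
  # AF 0 variant has no control evidence
  expect_equal(compute_pafv(list(chrom = "ctg1", start = 10001, end = 14000,
                                 svtype = "DEL", cnv = TRUE), coh$db), 0)
})
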