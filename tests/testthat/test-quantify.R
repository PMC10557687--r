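make_layouts <- function() {
  list(plain = default_layout("gdna"), umi = default_layout("gdna", umi = TRUE))
}

# build a barcode-count read: optional UMI + flank + barcode + flank
bc_read <- function(barcode, umi = NULL) {
  paste0(if (!is.null(umi)) umi else "", "ACTTCCGG", barcode, "GTTCTAGA")
}

test_that("UMI mode counts distinct barcode-UMI combinations", {
  lay <- make_layouts()
  bc <- "AAACAACAACAACAACAACAACAA"
  linkage <- tibble::tibble(barcode = bc, insert_id = "A", reads = 10L)
  # 5 reads, same UMI -> 1; 5 reads, 3 distinct UMIs -> 3
  same <- rep(bc_read(bc, "AAAAAAA"), 5)
  out1 <- count_barcodes(same, linkage, lay$umi, umi = TRUE)
  expect_equal(out1$count, 1)
  three <- bc_read(bc, c("AAAAAAA", "AAAAAAA", "CCCCCCC", "GGGGGGG",
                         "CCCCCCC"))
  out3 <- count_barcodes(three, linkage, lay$umi, umi = TRUE)
  expect_equal(out3$count, 3)
  # without UMI mode the same reads count as raw reads
  out5 <- count_barcodes(three, linkage, lay$umi, umi = FALSE)
  expect_equal(out5$count, 5)
  expect_error(count_barcodes(three, linkage, lay$plain, umi = TRUE),
               "umi")
})

test_that("barcodes absent from the linkage table are dropped and counted", {
  lay <- make_layouts()$plain
  linkage <- tibble::tibble(barcode = "AAACAACAACAACAACAACAACAA",
                            insert_id = "A", reads = 10L)
  reads <- c(bc_read("AAACAACAACAACAACAACAACAA"),
             bc_read("CCCACCACCACCACCACCACCACC"))
  out <- count_barcodes(reads, linkage, lay)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "provenance")$reads_unknown_barcode, 1)
})

test_that("counting is idempotent on re-run", {
  run <- make_mini_run(n_inserts = 12, seed = 41, depth = 8e4)
  a <- count_barcodes(run$fq[2], run$linkage)
  b <- count_barcodes(run$fq[2], run$linkage)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("insert counting recovers all distinct DMS sequences noise-free", {
  set.seed(42)
  dms <- dms_library()
  tr <- simulate_truth(dms, barcodes_per_insert = 1, bottleneck = 1,
                       spikeins = FALSE,
                       effects = effect_config(sigma_neutral = 0,
                                               p_destab = 0))
  tr$clones$abundance <- 1
  fq <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(tr, fq, "dms_gdna", depth = 20 * nrow(tr$clones),
                 error_rate = 0, noise_free = TRUE)
  out <- count_inserts(fq, dms, umi = TRUE)
  expect_equal(nrow(out), length(unique(dms$insert_seq)))
  # single read -> count 1; mutated insert -> dropped
  one <- paste0("AAAAAAA", "ACTTCCGG", dms$insert_seq[17])
  got <- count_inserts(one, dms, umi = TRUE)
  expect_equal(got$count, 1)
  # mutate a backbone codon of a position-1 mutant: the double mutant
  # matches no design sequence (a single substitution would merely map to
  # a different single-codon variant, which is itself in the reference)
  mut <- one
  substr(mut, 19, 19) <- "C" # second codon, backbone AAA -> CAA
  got2 <- count_inserts(mut, dms, umi = TRUE)
  expect_equal(nrow(got2), 0)
  expect_equal(attr(got2, "provenance")$reads_unmatched_insert, 1)
})

test_that("count filters enforce read and barcode minimums", {
  gdna <- tibble::tibble(
    barcode = c("b1", "b2", "b3", "b4"),
    insert_id = c("A", "A", "B", "B"),
    count = c(9L, 50L, 40L, 30L)
  )
  mrna <- tibble::tibble(
    barcode = c("b1", "b2", "b3", "b4"),
    insert_id = c("A", "A", "B", "B"),
    count = c(100L, 80L, 60L, 40L)
  )
  # b1 fails the 10-read gDNA cutoff; insert A then has 1 barcode < 2
  out <- filter_counts(mrna, gdna, min_reads = 10, min_barcodes = 2)
  expect_setequal(out$insert_id, "B")
  expect_setequal(out$barcode, c("b3", "b4"))
  # min_barcodes = 1 keeps insert A's surviving barcode
  out1 <- filter_counts(mrna, gdna, min_reads = 10, min_barcodes = 1)
  expect_true("A" %in% out1$insert_id)
  # cv_max = Inf equals no variability filter
  out_inf <- filter_counts(mrna, gdna, min_reads = 10, min_barcodes = 2,
                           cv_max = Inf)
  expect_equal(out_inf, out, ignore_attr = TRUE)
  expect_error(filter_counts(mrna, gdna, min_barcodes = 0), "min_barcodes")
  # monotone: raising min_reads never adds barcodes
  n_at <- vapply(c(1, 10, 31, 41, 51), function(mr) {
    nrow(filter_counts(mrna, gdna, min_reads = mr, min_barcodes = 1))
  }, integer(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("the variability filter removes high-CV inserts when enabled", {
  gdna <- tibble::tibble(
    barcode = paste0("b", 1:4),
    insert_id = c("A", "A", "B", "B"),
    count = c(100L, 100L, 100L, 100L)
  )
  mrna <- tibble::tibble(
    barcode = paste0("b", 1:4),
    insert_id = c("A", "A", "B", "B"),
    count = c(200L, 200L, 400L, 25L) # B's barcodes disagree wildly
  )
  out <- filter_counts(mrna, gdna, min_reads = 10, min_barcodes = 2,
                       cv_max = 0.5)
  expect_setequal(out$insert_id, "A")
})

test_that("bootstrap level is exact for degenerate inserts", {
  # single barcode: resampling is constant
  est <- estimate_mrna_level(40, 10, B = 100)
  expect_equal(est$level, 2)
  expect_equal(est$spread, 0)
  # all barcodes with m = g: level 0, spread 0
  est0 <- estimate_mrna_level(c(7, 13, 20), c(7, 13, 20), B = 200)
  expect_equal(est0$level, 0)
  expect_equal(est0$spread, 0)
  expect_error(estimate_mrna_level(numeric(0), numeric(0)), "empty")
})

test_that("bootstrap mean matches exact resample enumeration", {
  # two barcodes (40,10) and (10,40): the 4 equally likely resamples give
  # levels {2, 0, 0, -2}, so the exact expectation is 0
  m <- c(40, 10)
  g <- c(10, 40)
  expect_equal(exact_bootstrap_mean(m, g), 0)
  set.seed(51)
  est <- estimate_mrna_level(m, g, B = 10000)
  # SE of the Monte-Carlo mean ~ sd/sqrt(B); sd here is sqrt(2)
  expect_lt(abs(est$level - 0), 3 * sqrt(2) / sqrt(10000))
  # a second asymmetric fixture, enumerated independently
  m2 <- c(30, 10)
  g2 <- c(10, 10)
  exact2 <- exact_bootstrap_mean(m2, g2)
  set.seed(52)
  est2 <- estimate_mrna_level(m2, g2, B = 20000)
  expect_lt(abs(est2$level - exact2), 3 * est2$spread / sqrt(20000))
})

test_that("zero-mRNA resamples yield missing levels unless a pseudocount is set", {
  set.seed(53)
  est <- estimate_mrna_level(c(0, 0), c(10, 10), B = 50)
  expect_true(is.na(est$level))
  expect_true(est$zero_mrna)
  est_pc <- estimate_mrna_level(c(0, 0), c(10, 10), B = 50,
                                pseudocount = 0.5)
  expect_equal(est_pc$level, log2(0.5 / 20.5))
  expect_false(est_pc$zero_mrna)
})

test_that("normalization modes shift levels as documented", {
  lv <- tibble::tibble(
    insert_id = c("a", "b", "c", "sp"),
    level = c(1, 2, 3, 0),
    spread = 0, n_barcodes = 3L, zero_mrna = FALSE
  )
  med <- normalize_levels(lv[1:3, ], "median")
  expect_equal(med$level, c(-1, 0, 1))
  expect_equal(stats::median(med$level), 0, tolerance = 1e-12)
  # spike-in at level 0 leaves levels unchanged
  sp <- normalize_levels(lv, "spikein", spikeins = "sp")
  expect_equal(sp$level, lv$level)
  expect_error(normalize_levels(lv, "spikein"), "spike-in")
  expect_error(normalize_levels(lv, "spikein", spikeins = "zz"),
               "no spike-in")
  # rpm uses the recorded totals
  attr(lv, "totals") <- c(mrna = 2e6, gdna = 1e6)
  rpm <- normalize_levels(lv, "rpm")
  expect_equal(rpm$level, lv$level + log2(1e6 / 2e6))
})

test_that("global mRNA scaling shifts levels uniformly and median-cancels", {
  run <- make_mini_run(n_inserts = 10, seed = 54, depth = 6e4)
  g <- count_barcodes(run$fq[2], run$linkage)
  m <- count_barcodes(run$fq[3], run$linkage)
  paired <- filter_counts(m, g, min_barcodes = 1)
  set.seed(1)
  lv1 <- quantify_inserts(paired, B = 100)
  scaled <- paired
  scaled$mrna <- scaled$mrna * 8L
  set.seed(1)
  lv2 <- quantify_inserts(scaled, B = 100)
  expect_equal(lv2$level, lv1$level + 3, tolerance = 1e-9)
  expect_equal(normalize_levels(lv2, "median")$level,
               normalize_levels(lv1, "median")$level, tolerance = 1e-9)
  # bootstrap spread vanishes when barcode ratios are identical
  const <- paired
  const$mrna <- const$gdna * 4L
  lvc <- quantify_inserts(const, B = 100)
  expect_true(all(lvc$spread == 0))
  expect_true(all(lvc$level == 2))
})
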