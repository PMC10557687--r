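# UMI-count fixture builder: long count table for dms_levels
dms_counts <- function(design, mrna, gdna, replicates = 1:2,
                       spike_seq = NULL, spike_mrna = NULL,
                       spike_gdna = NULL) {
  seqs <- unique(design$insert_seq)
  stopifnot(length(mrna) == length(seqs))
  out <- purrr::map_dfr(replicates, function(r) {
    dplyr::bind_rows(
      tibble::tibble(insert_seq = seqs, replicate = r, sample = "mrna",
                     count = mrna),
      tibble::tibble(insert_seq = seqs, replicate = r, sample = "gdna",
                     count = gdna)
    )
  })
  if (!is.null(spike_seq)) {
    out <- dplyr::bind_rows(out, purrr::map_dfr(replicates, function(r) {
      dplyr::bind_rows(
        tibble::tibble(insert_seq = spike_seq, replicate = r,
                       sample = "mrna", count = spike_mrna),
        tibble::tibble(insert_seq = spike_seq, replicate = r,
                       sample = "gdna", count = spike_gdna)
      )
    }))
  }
  out
}

test_that("DMS levels are replicate-averaged log2 UMI ratios", {
  design <- dms_library()
  seqs <- unique(design$insert_seq)
  # equal mRNA and gDNA UMIs everywhere, spike-in at level 0: all levels 0
  counts <- dms_counts(design, mrna = rep(8L, length(seqs)),
                       gdna = rep(8L, length(seqs)),
                       spike_seq = "A", spike_mrna = 4L, spike_gdna = 4L)
  lv <- dms_levels(counts, design, spikeins = "A")
  expect_equal(nrow(lv), 1009) # 1008 mutants + collapsed wild-type row
  expect_true(all(lv$level == 0))
  expect_equal(lv$n_replicates, rep(2L, nrow(lv)))
  # doubling all mRNA UMIs including spike-ins cancels in normalization
  counts2 <- counts
  counts2$count[counts2$sample == "mrna"] <-
    counts2$count[counts2$sample == "mrna"] * 2L
  lv2 <- dms_levels(counts2, design, spikeins = "A")
  expect_equal(lv2$level, lv$level)
  expect_error(dms_levels(counts, design, spikeins = "ZZZ"), "spike-in")
})

test_that("noise-free DMS simulation recovers injected effects exactly", {
  design <- dms_library()
  set.seed(71)
  tr <- simulate_truth(design, barcodes_per_insert = 1, bottleneck = 1)
  tr$clones$abundance <- 1
  # dyadic effects so expected read counts are integers
  collapsed_seq <- unique(tr$inserts$insert_seq)
  eff <- stats::setNames(
    rep_len(c(0, -1, -2, 1), length(tr$inserts$insert_id)),
    tr$inserts$insert_id
  )
  eff[tr$inserts$class == "spikein"] <- 0
  tr$inserts$effect <- unname(eff[tr$inserts$insert_id])
  dir <- withr::local_tempdir()
  n <- nrow(tr$clones)
  fqm <- file.path(dir, "m.fastq")
  fqg <- file.path(dir, "g.fastq")
  simulate_reads(tr, fqg, "dms_gdna", depth = 8 * n, error_rate = 0,
                 noise_free = TRUE)
  simulate_reads(tr, fqm, "dms_mrna",
                 depth = sum(8 * 2^tr$inserts$effect[match(
                   tr$clones$insert_id, tr$inserts$insert_id)]),
                 error_rate = 0, noise_free = TRUE)
  # raw-read counting: UMI deduplication would introduce rare random
  # 7-mer collisions, which are a real phenomenon but break exactness
  ref <- tr$inserts[, c("insert_id", "insert_seq")]
  cm <- count_inserts(fqm, ref, umi = FALSE)
  cg <- count_inserts(fqg, ref, umi = FALSE)
  counts <- dplyr::bind_rows(
    dplyr::mutate(cm, replicate = 1L, sample = "mrna"),
    dplyr::mutate(cg, replicate = 1L, sample = "gdna"),
    dplyr::mutate(cm, replicate = 2L, sample = "mrna"),
    dplyr::mutate(cg, replicate = 2L, sample = "gdna")
  )
  spike_seqs <- tr$inserts$insert_seq[tr$inserts$class == "spikein"]
  lv <- dms_levels(counts, design, spikeins = spike_seqs)
  # wild-type duplicates share the backbone sequence; compare mutants
  mut <- lv[lv$variant_id != "WT", ]
  truth_eff <- eff[mut$variant_id]
  expect_equal(mut$level, unname(truth_eff), tolerance = 1e-9)
})

test_that("the DMS matrix averages synonymous codons and marks wild type", {
  design <- dms_library()
  seqs <- unique(design$insert_seq)
  counts <- dms_counts(design, mrna = rep(4L, length(seqs)),
                       gdna = rep(4L, length(seqs)), replicates = 1)
  lv <- dms_levels(counts, design)
  # inject a synonymous-consistent effect: all Leu codons at position 5
  leu <- design$variant_id[design$position == 5 & design$amino_acid == "L"]
  lv$level[lv$variant_id %in% leu] <- -1.5
  mat <- dms_matrix(lv, design)
  expect_equal(nrow(mat), 16 * 21)
  cell <- mat[mat$position == 5 & mat$amino_acid == "L", ]
  expect_equal(cell$level, -1.5)
  expect_equal(cell$n_codons, 6) # six leucine codons
  # stop row aggregates 3 codons per position
  stops <- mat[mat$amino_acid == "*", ]
  expect_true(all(stops$n_codons == 3))
  # wild-type marking: F at odd positions, K at even
  wt <- mat[mat$is_wildtype, ]
  expect_equal(nrow(wt), 16)
  expect_equal(wt$amino_acid[wt$position %% 2 == 1], rep("F", 8))
  expect_equal(wt$amino_acid[wt$position %% 2 == 0], rep("K", 8))
  # invariance to synonymous relabeling: permuting levels within a
  # synonymous group leaves the cell mean unchanged
  syn <- design$variant_id[design$position == 3 & design$amino_acid == "R"]
  lv_perm <- lv
  idx <- match(syn, lv_perm$variant_id)
  lv_perm$level[idx] <- lv_perm$level[rev(idx)]
  expect_equal(dms_matrix(lv_perm, design)$level, mat$level)
})

test_that("rank-sum p-values match exhaustive permutation enumeration", {
  # the textbook {1,2,3} vs {4,5,6} case: exact two-sided p = 0.1
  expect_equal(dicodon:::ranksum_test(1:3, 4:6)$p_value, 0.1)
  expect_equal(perm_ranksum_p(1:3, 4:6), 0.1)
  # identical samples: p = 1
  expect_equal(dicodon:::ranksum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # all two-group splits of small tie-free samples agree with the oracle
  set.seed(81)
  for (rep in 1:20) {
    n_total <- sample(5:8, 1)
    m <- sample(2:(n_total - 2), 1)
    vals <- sample(1:50, n_total) # distinct -> no ties
    x <- vals[seq_len(m)]
    y <- vals[-seq_len(m)]
    got <- dicodon:::ranksum_test(x, y)
    expect_true(got$exact)
    expect_equal(got$p_value, perm_ranksum_p(x, y), tolerance = 1e-12)
  }
  # large or tied samples fall back to the corrected normal approximation
  big <- dicodon:::ranksum_test(stats::rnorm(15), stats::rnorm(15))
  expect_false(big$exact)
})

test_that("position-wise tests flag indistinguishable positions", {
  design <- dms_library()
  seqs <- unique(design$insert_seq)
  counts <- dms_counts(design, mrna = rep(4L, length(seqs)),
                       gdna = rep(4L, length(seqs)), replicates = 1)
  lv <- dms_levels(counts, design)
  set.seed(82)
  lv$level <- stats::rnorm(nrow(lv), 0, 0.1)
  lv_mut <- lv
  # shift positions 1-6 strongly in the "mutant"
  sel <- !is.na(lv_mut$position) & lv_mut$position <= 6
  lv_mut$level[sel] <- lv_mut$level[sel] + 3
  out <- positionwise_test(lv, lv_mut, alpha = 0.01)
  expect_equal(nrow(out), 16)
  expect_true(all(!out$not_different[out$position <= 6]))
  expect_true(all(out$not_different[out$position > 6]))
  # stop variants are excluded from the comparison
  expect_true(all(out$n_a == 60)) # 61 sense codons incl. backbone aa,
                                  # minus the collapsed wild-type codon
  # identical inputs: p = 1 everywhere
  same <- positionwise_test(lv, lv)
  expect_true(all(same$p_value == 1))
  expect_true(all(same$not_different))
})

test_that("replicate correlation reflects shared signal", {
  design <- dms_library()
  seqs <- unique(design$insert_seq)
  counts <- dms_counts(design, mrna = rep(4L, length(seqs)),
                       gdna = rep(4L, length(seqs)))
  lv <- dms_levels(counts, design)
  long <- attr(lv, "per_replicate")
  set.seed(83)
  signal <- stats::rnorm(length(unique(long$variant_id)), 0, 1)
  names(signal) <- unique(long$variant_id)
  # identical replicates: r = 1; negated: r = -1
  long$level <- unname(signal[long$variant_id])
  expect_equal(replicate_correlation(long)$r, 1)
  long2 <- long
  long2$level[long2$replicate == 2] <- -long2$level[long2$replicate == 2]
  expect_equal(replicate_correlation(long2)$r, -1)
  # independent noise attenuates r toward s2/(s2 + n2)
  sigma_noise <- 0.5
  long3 <- long
  long3$level <- long3$level + stats::rnorm(nrow(long3), 0, sigma_noise)
  r <- replicate_correlation(long3)$r
  expected <- 1 / (1 + sigma_noise^2)
  expect_lt(abs(r - expected), 0.08)
  # degenerate variance is flagged, not an error
  long4 <- long
  long4$level <- 0
  expect_warning(rc <- replicate_correlation(long4), "degenerate")
  expect_true(is.na(rc$r))
})
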