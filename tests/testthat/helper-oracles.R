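# Independent oracles used across test files. These deliberately use naive
# O(n^2) / exhaustive strategies and never share code with the package
# implementations they check.

# Collision filter oracle: full pairwise edit-distance matrix, then the
# stated rule applied literally — drop multi-insert barcodes, then drop the
# lower-count member of every remaining pair within max_dist (ties: keep
# the lexicographically smaller string).
brute_collision_filter <- function(pairs, max_dist = 2L) {
  agg <- aggregate(reads ~ barcode + insert_id, data = as.data.frame(pairs),
                   FUN = sum)
  n_ins <- tapply(agg$insert_id, agg$barcode,
                  function(x) length(unique(x)))
  keep_bc <- names(n_ins)[n_ins == 1L]
  agg <- agg[agg$barcode %in% keep_bc, ]
  agg <- agg[order(agg$barcode), ]
  if (max_dist > 0L && nrow(agg) > 1L) {
    d <- utils::adist(agg$barcode)
    losers <- logical(nrow(agg))
    for (i in seq_len(nrow(agg) - 1L)) {
      for (j in (i + 1L):nrow(agg)) {
        if (d[i, j] <= max_dist) {
          if (agg$reads[i] > agg$reads[j]) {
            losers[j] <- TRUE
          } else if (agg$reads[i] < agg$reads[j]) {
            losers[i] <- TRUE
          } else if (agg$barcode[i] < agg$barcode[j]) {
            losers[j] <- TRUE
          } else {
            losers[i] <- TRUE
          }
        }
      }
    }
    agg <- agg[!losers, ]
  }
  agg <- agg[order(agg$insert_id, agg$barcode), ]
  tibble::tibble(barcode = agg$barcode, insert_id = agg$insert_id,
                 reads = as.integer(agg$reads))
}

# Exhaustive two-sided rank-sum p-value: enumerate every assignment of the
# pooled values into groups of the observed sizes and count assignments
# whose |U - E[U]| is at least as extreme as observed.
perm_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  eu <- m * (length(y)) / 2
  combs <- utils::combn(n, m)
  us <- apply(combs, 2L, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mean(abs(us - eu) >= abs(u_obs - eu) - 1e-9)
}

# Exact bootstrap expectation for an insert with n barcodes: enumerate all
# n^n equally likely resample index vectors and average log2(sum m / sum g).
exact_bootstrap_mean <- function(m, g) {
  n <- length(m)
  grid <- do.call(expand.grid, rep(list(seq_len(n)), n))
  vals <- apply(as.matrix(grid), 1L, function(idx) {
    log2(sum(m[idx]) / sum(g[idx]))
  })
  mean(vals)
}

# Random stop-free toy ORFs of the given length, codon-aligned, named.
make_toy_orfs <- function(n, len = 300L, prefix = "orf") {
  sense <- codon_table()
  sense <- sense$codon[!sense$is_stop]
  seqs <- vapply(seq_len(n), function(i) {
    paste(c("ATG", sample(sense, len / 3 - 1, replace = TRUE)),
          collapse = "")
  }, character(1))
  stats::setNames(seqs, paste0(prefix, seq_len(n)))
}

# Simulated FASTQ + truth for a small codon-pair subset, returned with the
# linkage/count tables ready for quantification tests.
make_mini_run <- function(n_inserts = 32, seed = 42, depth = 1.5e5,
                          error_rate = 0, dispersion = 0.2,
                          noise_free = FALSE) {
  withr::local_seed(seed)
  lib <- utils::head(codon_pair_library(), n_inserts)
  truth <- simulate_truth(lib, barcodes_per_insert = 100, bottleneck = 0.2)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  fq <- file.path(dir, c("l.fastq", "g.fastq", "m.fastq"))
  simulate_reads(truth, fq[1], "linkage", depth = depth,
                 error_rate = error_rate, dispersion = dispersion,
                 noise_free = noise_free)
  simulate_reads(truth, fq[2], "gdna", depth = depth,
                 error_rate = error_rate, dispersion = dispersion,
                 noise_free = noise_free)
  simulate_reads(truth, fq[3], "mrna", depth = depth,
                 error_rate = error_rate, dispersion = dispersion,
                 noise_free = noise_free)
  reference <- rbind(
    lib[, c("insert_id", "insert_seq")],
    truth$inserts[truth$inserts$class == "spikein",
                  c("insert_id", "insert_seq")]
  )
  linkage <- filter_barcode_collisions(
    extract_linkage_pairs(fq[1], reference)
  )
  list(lib = lib, truth = truth, dir = dir, fq = fq,
       reference = reference, linkage = linkage)
}
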