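# Fixed spike-in clones: two strains of known insert and barcode carried
# through library growth at defined abundance, used for cross-sample
# normalisation. Sequences are stop-free in frame 0 and the barcodes are
# valid VNN repeats.
.SPIKEIN_INSERTS <- c(
  spikein_1 = paste(c("ATG", "GCT", "GAA", "GCC", "TTG", "TCT", "AAG", "GCA",
                      "GAG", "CTT", "TCC", "AAA", "GCG", "GAC", "TTA", "TCA"),
                    collapse = ""),
  spikein_2 = paste(c("ATG", "TCT", "CAA", "GTT", "GAC", "AAG", "CCA", "GAA",
                      "TTG", "GCT", "AGA", "TCC", "CAT", "GTC", "GGT", "TTC"),
                    collapse = "")
)
.SPIKEIN_BARCODES <- c(
  spikein_1 = "ATTCGGAACGTCCCAGATACGGGA",
  spikein_2 = "CAAGGTATCCTGGACAGTCCTGTA"
)

#' Effect-distribution configuration for simulated truth
#'
#' Per-insert true log2 mRNA effects are drawn from a three-class mixture:
#' most inserts are neutral (centred at 0), a fraction is destabilized
#' (ribosome-stalling class, mean `mu_destab`), and stop-codon-containing
#' inserts form a separate NMD class. Defaults reflect a library in which
#' strong destabilization (around -2 log2 units) affects a minority of
#' dipeptides and stop-containing inserts are degraded at least as strongly.
#'
#' @param sigma_neutral SD of the neutral class (log2 units).
#' @param p_destab Probability that a stop-free insert is destabilized.
#' @param mu_destab,sigma_destab Mean/SD of the destabilized class.
#' @param mu_nmd,sigma_nmd Mean/SD of the stop-codon (NMD) class.
#' @return A named list of class `effect_config`.
#' @export
effect_config <- function(sigma_neutral = 0.2, p_destab = 0.1,
                          mu_destab = -2, sigma_destab = 0.5,
                          mu_nmd = -3, sigma_nmd = 0.5) {
  if (p_destab < 0 || p_destab > 1) {
    stop("p_destab must be a probability in [0, 1]")
  }
  stopifnot(sigma_neutral >= 0, sigma_destab >= 0, sigma_nmd >= 0)
  structure(
    list(sigma_neutral = sigma_neutral, p_destab = p_destab,
         mu_destab = mu_destab, sigma_destab = sigma_destab,
         mu_nmd = mu_nmd, sigma_nmd = sigma_nmd),
    class = "effect_config"
  )
}

#' Simulate ground-truth effects and clone structure for a library
#'
#' Assigns each insert a true log2 mRNA effect from the mixture in
#' [effect_config()], draws barcoded clones per insert (a binomial
#' bottleneck of the plasmid pool, emulating genomic integration), gives
#' each clone a log-normal abundance, and injects spike-in clones of known
#' effect 0. Uses the current RNG state.
#'
#' @param library Design tibble with `insert_id` and `insert_seq` columns
#'   (e.g. [codon_pair_library()] or [dms_library()]; a `variant_id` column
#'   is accepted as the id).
#' @param barcodes_per_insert Plasmid barcodes per insert before the
#'   bottleneck (default 100).
#' @param bottleneck Probability that a plasmid clone survives integration
#'   (default 0.2, so the median surviving clones per insert is about 20).
#' @param effects An [effect_config()].
#' @param spikeins Add the two fixed spike-in clones (default TRUE).
#' @return A `sim_truth` object: list with tibbles `inserts` (`insert_id`,
#'   `insert_seq`, `class`, `effect`) and `clones` (`barcode`, `insert_id`,
#'   `abundance`, `is_spikein`).
#' @export
simulate_truth <- function(library, barcodes_per_insert = 100L,
                           bottleneck = 0.2, effects = effect_config(),
                           spikeins = TRUE) {
  stopifnot(is.data.frame(library), "insert_seq" %in% names(library))
  if (!inherits(effects, "effect_config")) {
    effects <- do.call(effect_config, effects)
  }
  id_col <- intersect(c("insert_id", "variant_id"), names(library))[1]
  if (is.na(id_col)) stop("library needs an insert_id or variant_id column")
  ins <- tibble::tibble(
    insert_id  = library[[id_col]],
    insert_seq = library$insert_seq
  )
  n <- nrow(ins)
  has_stop <- has_frame0_stop(ins$insert_seq)
  destab <- !has_stop & stats::runif(n) < effects$p_destab
  ins$class <- dplyr::case_when(
    has_stop ~ "nmd",
    destab   ~ "destabilized",
    TRUE     ~ "neutral"
  )
  ins$effect <- stats::rnorm(
    n,
    mean = c(neutral = 0, destabilized = effects$mu_destab,
             nmd = effects$mu_nmd)[ins$class],
    sd   = c(neutral = effects$sigma_neutral,
             destabilized = effects$sigma_destab,
             nmd = effects$sigma_nmd)[ins$class]
  )

  n_clones <- stats::rbinom(n, size = barcodes_per_insert, prob = bottleneck)
  total <- sum(n_clones)
  bc <- generate_barcodes(total)
  while (anyDuplicated(bc) > 0L) {
    dup <- duplicated(bc)
    bc[dup] <- generate_barcodes(sum(dup))
  }
  clones <- tibble::tibble(
    barcode    = bc,
    insert_id  = rep(ins$insert_id, n_clones),
    abundance  = stats::rlnorm(total, meanlog = 0, sdlog = 1),
    is_spikein = FALSE
  )

  if (spikeins) {
    ins <- dplyr::bind_rows(ins, tibble::tibble(
      insert_id  = names(.SPIKEIN_INSERTS),
      insert_seq = unname(.SPIKEIN_INSERTS),
      class      = "spikein",
      effect     = 0
    ))
    clones <- dplyr::bind_rows(clones, tibble::tibble(
      barcode    = unname(.SPIKEIN_BARCODES),
      insert_id  = names(.SPIKEIN_BARCODES),
      abundance  = 1,
      is_spikein = TRUE
    ))
  }
  structure(list(inserts = ins, clones = clones), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$inserts), " inserts, ", nrow(x$clones),
      " clones (", sum(x$clones$is_spikein), " spike-in)\n", sep = "")
  invisible(x)
}

#' Simulate amplicon sequencing reads as FASTQ
#'
#' Draws per-clone read counts and writes reads assembled from the layout
#' segments. Linkage and gDNA reads are drawn proportional to clone
#' abundance a; cDNA (mRNA) reads proportional to a * 2^effect. Counts
#' follow a gamma-Poisson (negative binomial) with dispersion `dispersion`;
#' `noise_free = TRUE` instead emits exactly `round()` of the expected
#' count per clone. Per-base substitution errors are applied at
#' `error_rate`. Quality strings are constant and never used downstream.
#'
#' @param truth A [simulate_truth()] object.
#' @param file Output FASTQ path (gzip if it ends in `.gz`).
#' @param type Sample type: `"linkage"`, `"gdna"`, `"mrna"`, `"dms_gdna"`,
#'   or `"dms_mrna"`.
#' @param depth Total expected read count (> 0).
#' @param dispersion Gamma-Poisson dispersion phi (0 = Poisson).
#' @param error_rate Per-base substitution probability.
#' @param noise_free Deterministic expected counts (rounded), no
#'   overdispersion or Poisson noise.
#' @param layout A [read_layout()]; defaults to [default_layout()] for the
#'   sample type.
#' @return Invisibly, a tibble of per-clone true read counts (`barcode`,
#'   `insert_id`, `reads`).
#' @export
simulate_reads <- function(truth, file,
                           type = c("linkage", "gdna", "mrna",
                                    "dms_gdna", "dms_mrna"),
                           depth = 1e5, dispersion = 0.3, error_rate = 1e-3,
                           noise_free = FALSE,
                           layout = default_layout(type)) {
  type <- match.arg(type)
  stopifnot(inherits(truth, "sim_truth"))
  if (depth <= 0) stop("depth must be positive")
  stopifnot(dispersion >= 0, error_rate >= 0, error_rate < 1)

  clones <- dplyr::left_join(
    truth$clones,
    truth$inserts[, c("insert_id", "insert_seq", "effect")],
    by = "insert_id"
  )
  w <- switch(type,
    linkage  = clones$abundance,
    gdna     = clones$abundance,
    dms_gdna = clones$abundance,
    mrna     = clones$abundance * 2^clones$effect,
    dms_mrna = clones$abundance * 2^clones$effect
  )
  mu <- depth * w / sum(w)
  counts <- if (noise_free) {
    as.integer(round(mu))
  } else {
    lambda <- if (dispersion > 0) {
      mu * stats::rgamma(length(mu), shape = 1 / dispersion,
                         rate = 1 / dispersion)
    } else {
      mu
    }
    stats::rpois(length(mu), lambda)
  }

  idx <- rep(seq_len(nrow(clones)), counts)
  n_reads <- length(idx)
  segs <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    seg <- layout$segment[i]
    segs[[i]] <- if (!is.na(layout$fixed_seq[i])) {
      rep(layout$fixed_seq[i], n_reads)
    } else if (seg == "insert") {
      clones$insert_seq[idx]
    } else if (seg == "barcode") {
      clones$barcode[idx]
    } else if (seg == "umi") {
      random_umis(n_reads, layout$width[i])
    } else {
      stop("layout segment '", seg, "' has no source in the simulation")
    }
  }
  reads <- do.call(paste0, segs)
  if (error_rate > 0 && n_reads > 0) {
    reads <- inject_errors(reads, error_rate)
  }
  write_fastq(reads, file)
  invisible(tibble::tibble(
    barcode = clones$barcode, insert_id = clones$insert_id, reads = counts
  ))
}

# uniform random UMIs of the given width; saturation at high depth arises
# naturally because distinct molecules can draw the same UMI
random_umis <- function(n, width = 7L) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = width)
  apply(m, 2L, paste, collapse = "")
}

# per-base substitution errors; draws the number of hits per read, then
# mutates one position per pass (a position can be hit twice, slightly
# undercounting at high rates, which is immaterial at the rates used)
inject_errors <- function(seqs, rate) {
  len <- nchar(seqs)
  hits <- stats::rbinom(length(seqs), size = len, prob = rate)
  if (all(hits == 0L)) return(seqs)
  bases <- c("A", "C", "G", "T")
  for (pass in seq_len(max(hits))) {
    sel <- which(hits >= pass)
    pos <- ceiling(stats::runif(length(sel)) * len[sel])
    orig <- substr(seqs[sel], pos, pos)
    shift <- sample.int(3L, length(sel), replace = TRUE)
    repl <- bases[(match(orig, bases) - 1L + shift) %% 4L + 1L]
    x <- seqs[sel]
    substr(x, pos, pos) <- repl
    seqs[sel] <- x
  }
  seqs
}

#' Write and read FASTQ files
#'
#' Minimal FASTQ I/O for simulated amplicon reads: constant quality on
#' write; qualities ignored on read (the analysis never uses them).
#' `read_fastq()` parses via Biostrings.
#'
#' @param reads Character vector of read sequences.
#' @param file FASTQ path; gzip-compressed if it ends in `.gz`.
#' @return `read_fastq()`: character vector of read sequences.
#' @export
write_fastq <- function(reads, file) {
  n <- length(reads)
  con <- if (grepl("\\.gz$", file)) gzfile(file, "wb") else file(file, "wb")
  on.exit(close(con))
  if (n == 0L) {
    writeLines(character(0), con)
    return(invisible(file))
  }
  lines <- as.vector(rbind(
    paste0("@read_", seq_len(n)),
    reads,
    "+",
    strrep("I", nchar(reads))
  ))
  writeLines(lines, con)
  invisible(file)
}

#' @rdname write_fastq
#' @param file FASTQ path.
#' @export
read_fastq <- function(file) {
  info <- file.info(file)
  if (!is.na(info$size) && info$size == 0) return(character(0))
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  unname(as.character(x))
}

#' Serialize and restore a simulation truth object
#'
#' Writes `inserts.csv` and `clones.csv` under `dir` with full double
#' precision so the round trip is exact.
#'
#' @param truth A `sim_truth` object.
#' @param dir Directory (created if needed).
#' @return `read_truth()`: the restored `sim_truth`.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ins <- truth$inserts
  ins$effect <- sprintf("%.17g", ins$effect)
  readr::write_csv(ins, file.path(dir, "inserts.csv"))
  cl <- truth$clones
  cl$abundance <- sprintf("%.17g", cl$abundance)
  readr::write_csv(cl, file.path(dir, "clones.csv"))
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  # doubles travel as %.17g strings and come back through strtod, which is
  # correctly rounded, so the round trip is bit-exact
  ins <- readr::read_csv(
    file.path(dir, "inserts.csv"),
    col_types = readr::cols(
      insert_id = "c", insert_seq = "c", class = "c", effect = "c"
    )
  )
  ins$effect <- as.numeric(ins$effect)
  cl <- readr::read_csv(
    file.path(dir, "clones.csv"),
    col_types = readr::cols(
      barcode = "c", insert_id = "c", abundance = "c", is_spikein = "l"
    )
  )
  cl$abundance <- as.numeric(cl$abundance)
  structure(list(inserts = ins, clones = cl), class = "sim_truth")
}
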