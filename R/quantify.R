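#' Count barcodes in a gDNA or cDNA sample
#'
#' Extracts the barcode (and UMI, when the layout has one and `umi = TRUE`)
#' from each read, keeps barcodes present in the linkage table, and counts
#' either raw reads or distinct (barcode, UMI) combinations per barcode.
#'
#' @param fastq FASTQ path or character vector of read sequences.
#' @param linkage Filtered linkage table from
#'   [filter_barcode_collisions()].
#' @param layout A [read_layout()] with a `barcode` segment (and `umi` if
#'   `umi = TRUE`).
#' @param umi Count distinct barcode-UMI combinations instead of reads.
#' @return A tibble (`barcode`, `insert_id`, `count`), ordered by
#'   `insert_id` then `barcode`, with a `provenance` attribute.
#' @export
count_barcodes <- function(fastq, linkage, layout = default_layout("gdna"),
                           umi = FALSE) {
  stopifnot(is.data.frame(linkage),
            all(c("barcode", "insert_id") %in% names(linkage)))
  if (umi && !layout_has(layout, "umi")) {
    stop("umi = TRUE but the layout has no 'umi' segment")
  }
  reads <- if (length(fastq) == 1L && file.exists(fastq)) {
    read_fastq(fastq)
  } else {
    as.character(fastq)
  }
  n_parsed <- length(reads)
  ok <- nchar(reads) >= layout_width(layout)
  reads <- reads[ok]
  bc <- layout_extract(reads, layout, "barcode")
  known <- bc %in% linkage$barcode
  n_unknown <- sum(!known)
  if (umi) {
    u <- layout_extract(reads, layout, "umi")[known]
    tab <- tibble::tibble(barcode = bc[known], umi = u) |>
      dplyr::distinct() |>
      dplyr::count(.data$barcode, name = "count")
  } else {
    tab <- tibble::tibble(barcode = bc[known]) |>
      dplyr::count(.data$barcode, name = "count")
  }
  out <- tab |>
    dplyr::inner_join(linkage[, c("barcode", "insert_id")], by = "barcode") |>
    dplyr::arrange(.data$insert_id, .data$barcode) |>
    dplyr::select("barcode", "insert_id", "count")
  attr(out, "provenance") <- list(
    reads_parsed = n_parsed,
    reads_short = sum(!ok),
    reads_unknown_barcode = n_unknown
  )
  out
}

#' Count inserts directly (deep mutational scanning samples)
#'
#' For libraries sequenced through the insert rather than a barcode:
#' extracts the insert segment, keeps exact matches to the reference
#' sequences, and counts distinct (insert, UMI) combinations (or raw reads
#' when `umi = FALSE`). Counts are keyed by `insert_seq` because design
#' entries whose mutant codon equals the backbone codon share the backbone
#' sequence and cannot be distinguished by sequencing.
#'
#' @param fastq FASTQ path or character vector of read sequences.
#' @param reference Design tibble with an `insert_seq` column.
#' @param layout A [read_layout()] with an `insert` segment.
#' @param umi Deduplicate on distinct insert-UMI combinations
#'   (default TRUE).
#' @return A tibble (`insert_seq`, `count`) with a `provenance` attribute.
#' @export
count_inserts <- function(fastq, reference,
                          layout = default_layout("dms_mrna"), umi = TRUE) {
  stopifnot(is.data.frame(reference), "insert_seq" %in% names(reference))
  if (umi && !layout_has(layout, "umi")) {
    stop("umi = TRUE but the layout has no 'umi' segment")
  }
  reads <- if (length(fastq) == 1L && file.exists(fastq)) {
    read_fastq(fastq)
  } else {
    as.character(fastq)
  }
  n_parsed <- length(reads)
  ok <- nchar(reads) >= layout_width(layout)
  reads <- reads[ok]
  ins <- layout_extract(reads, layout, "insert")
  known <- ins %in% unique(reference$insert_seq)
  n_unmatched <- sum(!known)
  if (umi) {
    u <- layout_extract(reads, layout, "umi")[known]
    tab <- tibble::tibble(insert_seq = ins[known], umi = u) |>
      dplyr::distinct() |>
      dplyr::count(.data$insert_seq, name = "count")
  } else {
    tab <- tibble::tibble(insert_seq = ins[known]) |>
      dplyr::count(.data$insert_seq, name = "count")
  }
  out <- dplyr::arrange(tab, .data$insert_seq)
  attr(out, "provenance") <- list(
    reads_parsed = n_parsed,
    reads_short = sum(!ok),
    reads_unmatched_insert = n_unmatched
  )
  out
}

#' Pair and filter mRNA/gDNA barcode counts
#'
#' Joins the cDNA (mRNA) and genomic-DNA count tables on barcode, treating
#' barcodes absent from the mRNA sample as zero. Barcodes below `min_reads`
#' in the gDNA sample (the clone-abundance proxy) are removed, as are
#' barcodes below `min_reads_mrna` in the mRNA sample; inserts left with
#' fewer than `min_barcodes` barcodes are removed. An optional variability
#' filter removes inserts whose per-barcode log2 ratios have a coefficient
#' of variation (sd / |mean|) above `cv_max`.
#'
#' @param mrna,gdna Count tables from [count_barcodes()].
#' @param min_reads Minimum gDNA reads per barcode (default 10).
#' @param min_reads_mrna Minimum mRNA reads per barcode (default 0).
#' @param min_barcodes Minimum surviving barcodes per insert (default 2).
#' @param cv_max Maximum coefficient of variation of per-barcode log2
#'   ratios per insert (default `Inf`, disabled).
#' @return A tibble (`insert_id`, `barcode`, `mrna`, `gdna`) with attribute
#'   `totals` (total mRNA/gDNA counts before filtering, used for RPM
#'   normalization).
#' @export
filter_counts <- function(mrna, gdna, min_reads = 10L, min_reads_mrna = 0L,
                          min_barcodes = 2L, cv_max = Inf) {
  if (min_barcodes < 1L) stop("min_barcodes must be >= 1")
  totals <- c(mrna = sum(mrna$count), gdna = sum(gdna$count))
  paired <- gdna |>
    dplyr::select("barcode", "insert_id", gdna = "count") |>
    dplyr::left_join(dplyr::select(mrna, "barcode", mrna = "count"),
                     by = "barcode") |>
    dplyr::mutate(mrna = dplyr::coalesce(.data$mrna, 0L)) |>
    dplyr::filter(.data$gdna >= min_reads, .data$mrna >= min_reads_mrna)
  if (is.finite(cv_max)) {
    paired <- paired |>
      dplyr::group_by(.data$insert_id) |>
      dplyr::mutate(.ratio = log2(.data$mrna / .data$gdna)) |>
      dplyr::filter(
        dplyr::n() == 1L |
          dplyr::coalesce(
            stats::sd(.data$.ratio) / abs(mean(.data$.ratio)), Inf
          ) <= cv_max
      ) |>
      dplyr::ungroup() |>
      dplyr::select(-".ratio")
  }
  out <- paired |>
    dplyr::group_by(.data$insert_id) |>
    dplyr::filter(dplyr::n() >= min_barcodes) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$insert_id, .data$barcode) |>
    dplyr::select("insert_id", "barcode", "mrna", "gdna")
  attr(out, "totals") <- totals
  out
}

#' Bootstrap estimate of an insert's log2 mRNA level
#'
#' Resamples an insert's barcodes with replacement `B` times; each resample
#' yields `log2(sum(mrna) / sum(gdna))`. The level is the mean over
#' resamples and the spread the standard deviation. A resample with zero
#' summed mRNA yields a missing level unless a pseudocount is supplied
#' (added to both sums).
#'
#' @param mrna,gdna Equal-length numeric vectors of per-barcode counts
#'   (gdna all positive).
#' @param B Number of bootstrap resamples (default 100).
#' @param pseudocount Optional pseudocount added to both summed counts
#'   (`NULL` disables; 0.5 is the conventional choice when enabled).
#' @return A list with `level`, `spread`, `n_barcodes`, and `zero_mrna`
#'   (TRUE when a resample had zero mRNA and no pseudocount was in force).
#' @export
#' @examples
#' estimate_mrna_level(40, 10) # level 2, spread 0
estimate_mrna_level <- function(mrna, gdna, B = 100L, pseudocount = NULL) {
  n <- length(mrna)
  if (n == 0L) stop("empty barcode list")
  stopifnot(length(gdna) == n, all(gdna > 0), B >= 1)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  ms <- colSums(matrix(mrna[idx], nrow = n))
  gs <- colSums(matrix(gdna[idx], nrow = n))
  zero <- any(ms == 0)
  if (zero && is.null(pseudocount)) {
    return(list(level = NA_real_, spread = NA_real_, n_barcodes = n,
                zero_mrna = TRUE))
  }
  c0 <- if (is.null(pseudocount)) 0 else pseudocount
  ratios <- log2((ms + c0) / (gs + c0))
  list(level = mean(ratios), spread = stats::sd(ratios), n_barcodes = n,
       zero_mrna = zero && is.null(pseudocount))
}

#' Per-insert bootstrapped mRNA levels
#'
#' Applies [estimate_mrna_level()] to every insert of a filtered paired
#' count table. Uses the current RNG state; seed for reproducibility.
#'
#' @param counts Output of [filter_counts()].
#' @param B Bootstrap resamples per insert (default 100).
#' @param pseudocount See [estimate_mrna_level()].
#' @return A tibble (`insert_id`, `level`, `spread`, `n_barcodes`,
#'   `zero_mrna`), carrying forward the `totals` attribute and recording
#'   `normalization = "none"`.
#' @export
quantify_inserts <- function(counts, B = 100L, pseudocount = NULL) {
  stopifnot(all(c("insert_id", "barcode", "mrna", "gdna") %in% names(counts)))
  groups <- split(counts[, c("mrna", "gdna")], counts$insert_id)
  est <- lapply(groups, function(g) {
    estimate_mrna_level(g$mrna, g$gdna, B = B, pseudocount = pseudocount)
  })
  out <- tibble::tibble(
    insert_id  = names(groups),
    level      = vapply(est, `[[`, numeric(1), "level"),
    spread     = vapply(est, `[[`, numeric(1), "spread"),
    n_barcodes = vapply(est, `[[`, integer(1), "n_barcodes"),
    zero_mrna  = vapply(est, `[[`, logical(1), "zero_mrna")
  ) |>
    dplyr::arrange(.data$insert_id)
  attr(out, "totals") <- attr(counts, "totals")
  attr(out, "normalization") <- "none"
  out
}

#' Normalize per-insert mRNA levels
#'
#' `"median"` subtracts the library median level (the default for large
#' libraries, cancelling sequencing-depth differences); `"spikein"`
#' subtracts the mean level of the spike-in inserts (for cross-genotype
#' comparison); `"rpm"` rescales both samples to reads-per-million before
#' the ratio, i.e. shifts all levels by `log2(total_gdna / total_mrna)`;
#' `"none"` returns the table unchanged.
#'
#' @param levels A level table from [quantify_inserts()].
#' @param mode One of `"median"`, `"spikein"`, `"rpm"`, `"none"`.
#' @param spikeins Character vector of spike-in insert ids (required for
#'   `"spikein"` mode).
#' @return The level table with shifted `level` and the `normalization`
#'   attribute updated.
#' @export
normalize_levels <- function(levels,
                             mode = c("median", "spikein", "rpm", "none"),
                             spikeins = NULL) {
  mode <- match.arg(mode)
  shift <- switch(mode,
    none = 0,
    median = stats::median(levels$level, na.rm = TRUE),
    spikein = {
      if (is.null(spikeins)) stop("spikein mode requires spike-in ids")
      sp <- levels$level[levels$insert_id %in% spikeins]
      sp <- sp[is.finite(sp)]
      if (length(sp) == 0L) stop("no spike-in inserts found in level table")
      mean(sp)
    },
    rpm = {
      totals <- attr(levels, "totals")
      if (is.null(totals)) stop("rpm mode requires the 'totals' attribute")
      -log2(totals[["gdna"]] / totals[["mrna"]])
    }
  )
  levels$level <- levels$level - shift
  attr(levels, "normalization") <- mode
  levels
}
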