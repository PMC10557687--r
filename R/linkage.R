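#' Extract barcode-to-insert linkage pairs from linkage reads
#'
#' Pulls the insert and barcode segments out of each read and keeps only
#' pairs whose insert segment exactly matches a reference insert sequence.
#' Reads shorter than the layout, or with unmatched inserts, are dropped and
#' tallied in the `provenance` attribute.
#'
#' @param fastq Path to the linkage FASTQ file (or a character vector of
#'   read sequences).
#' @param reference Design tibble with `insert_seq` and an id column
#'   (`insert_id` or `variant_id`).
#' @param layout A [read_layout()] with `insert` and `barcode` segments.
#' @return A tibble of raw pair counts (`barcode`, `insert_id`, `reads`),
#'   ordered by `insert_id` then `barcode`, with attribute `provenance`
#'   (reads_parsed, reads_short, reads_unmatched_insert).
#' @export
extract_linkage_pairs <- function(fastq, reference,
                                  layout = default_layout("linkage")) {
  stopifnot(is.data.frame(reference), "insert_seq" %in% names(reference))
  id_col <- intersect(c("insert_id", "variant_id"), names(reference))[1]
  reads <- if (length(fastq) == 1L && file.exists(fastq)) {
    read_fastq(fastq)
  } else {
    as.character(fastq)
  }
  n_parsed <- length(reads)
  ok <- nchar(reads) >= layout_width(layout)
  n_short <- sum(!ok)
  reads <- reads[ok]
  insert <- layout_extract(reads, layout, "insert")
  barcode <- layout_extract(reads, layout, "barcode")
  hit <- match(insert, reference$insert_seq)
  n_unmatched <- sum(is.na(hit))
  keep <- !is.na(hit)
  out <- tibble::tibble(
    barcode   = barcode[keep],
    insert_id = reference[[id_col]][hit[keep]]
  ) |>
    dplyr::count(.data$insert_id, .data$barcode, name = "reads") |>
    dplyr::arrange(.data$insert_id, .data$barcode) |>
    dplyr::select("barcode", "insert_id", "reads")
  attr(out, "provenance") <- list(
    reads_parsed = n_parsed,
    reads_short = n_short,
    reads_unmatched_insert = n_unmatched
  )
  out
}

#' Filter barcode collisions from raw linkage pairs
#'
#' Applies two filters to raw (barcode, insert) read counts:
#' 1. barcodes observed with two or more distinct inserts are removed
#'    entirely (template switching / chimeras make their assignment
#'    ambiguous);
#' 2. among remaining barcodes, for every pair of barcodes within edit
#'    (Levenshtein) distance `max_dist`, the barcode with the lower read
#'    count is removed (it is most likely a sequencing-error shadow of the
#'    higher-count barcode). Ties keep the lexicographically smaller
#'    barcode. Every qualifying pair contributes a removal, which makes
#'    the filter deterministic, idempotent, and monotone in `max_dist`.
#'
#' Candidate near-duplicate pairs are found by pigeonhole 8-mer chunking
#' (complete for distance <= 2 on 24-nt barcodes) and verified with
#' [utils::adist()]; small inputs use the full distance matrix.
#'
#' @param pairs Raw pair counts from [extract_linkage_pairs()].
#' @param max_dist Maximum edit distance for near-duplicate removal
#'   (default 2; 0 disables the near-duplicate filter).
#' @param method Candidate-pair strategy: `"auto"` (full distance matrix
#'   below 1500 barcodes, chunked index above), `"matrix"`, or
#'   `"chunked"`. All give identical results; the choice only affects
#'   speed.
#' @return A linkage table tibble (`barcode`, `insert_id`, `reads`), one row
#'   per barcode, ordered by `insert_id` then `barcode`, with a
#'   `provenance` attribute recording the number of barcodes dropped by
#'   each filter.
#' @export
filter_barcode_collisions <- function(pairs, max_dist = 2L,
                                      method = c("auto", "matrix",
                                                 "chunked")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(pairs),
            all(c("barcode", "insert_id", "reads") %in% names(pairs)))
  stopifnot(max_dist >= 0)

  by_bc <- pairs |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(
      n_inserts = dplyr::n_distinct(.data$insert_id),
      insert_id = .data$insert_id[which.max(.data$reads)],
      reads     = sum(.data$reads),
      .groups   = "drop"
    )
  multi <- by_bc$n_inserts > 1L
  n_multi <- sum(multi)
  tab <- by_bc[!multi, c("barcode", "insert_id", "reads")]

  n_neardup <- 0L
  if (max_dist > 0L && nrow(tab) > 1L) {
    edges <- near_duplicate_pairs(tab$barcode, max_dist, method)
    if (nrow(edges) > 0L) {
      a <- edges$i
      b <- edges$j
      # loser: lower count; tie -> lexicographically larger string
      a_wins <- tab$reads[a] > tab$reads[b] |
        (tab$reads[a] == tab$reads[b] & tab$barcode[a] < tab$barcode[b])
      losers <- unique(ifelse(a_wins, b, a))
      n_neardup <- length(losers)
      tab <- tab[-losers, ]
    }
  }
  out <- dplyr::arrange(tab, .data$insert_id, .data$barcode)
  prov <- attr(pairs, "provenance")
  attr(out, "provenance") <- c(prov, list(
    barcodes_multi_insert = n_multi,
    barcodes_near_duplicate = n_neardup
  ))
  out
}

# All index pairs (i < j) of barcodes within edit distance max_dist.
# Full adist matrix below 1500 barcodes; otherwise pigeonhole candidate
# generation: any pair of equal-length strings within <= 2 edits shares an
# 8-mer chunk of one string appearing in the other at an offset shifted by
# at most max_dist, so indexing shifted windows finds all candidates.
near_duplicate_pairs <- function(barcodes, max_dist, method = "auto") {
  n <- length(barcodes)
  use_matrix <- switch(method, matrix = TRUE, chunked = FALSE,
                       auto = n <= 1500L)
  if (use_matrix) {
    d <- utils::adist(barcodes)
    hit <- which(d <= max_dist & upper.tri(d), arr.ind = TRUE)
    return(tibble::tibble(i = hit[, 1], j = hit[, 2]))
  }
  len <- nchar(barcodes[1])
  chunk <- 8L
  starts <- seq(1L, len - chunk + 1L, by = chunk)
  qkey <- ikey <- vector("list", 0L)
  for (s_i in seq_along(starts)) {
    s <- starts[s_i]
    qkey[[length(qkey) + 1L]] <- tibble::tibble(
      key = paste0(s_i, ":", substr(barcodes, s, s + chunk - 1L)),
      id  = seq_len(n)
    )
    for (off in -max_dist:max_dist) {
      s2 <- s + off
      if (s2 < 1L || s2 + chunk - 1L > len) next
      ikey[[length(ikey) + 1L]] <- tibble::tibble(
        key = paste0(s_i, ":", substr(barcodes, s2, s2 + chunk - 1L)),
        id  = seq_len(n)
      )
    }
  }
  q <- dplyr::bind_rows(qkey)
  ix <- dplyr::distinct(dplyr::bind_rows(ikey))
  cand <- dplyr::inner_join(q, ix, by = "key",
                            relationship = "many-to-many") |>
    dplyr::transmute(i = pmin(.data$id.x, .data$id.y),
                     j = pmax(.data$id.x, .data$id.y)) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::distinct()
  if (nrow(cand) == 0L) return(cand)
  d <- vapply(seq_len(nrow(cand)), function(r) {
    utils::adist(barcodes[cand$i[r]], barcodes[cand$j[r]])[1, 1]
  }, numeric(1))
  cand[d <= max_dist, ]
}

#' Read and write linkage tables
#'
#' Comma-delimited, header row, bit-stable ordering (insert_id, then
#' barcode).
#'
#' @param linkage A linkage tibble.
#' @param path CSV path.
#' @return `read_linkage()`: the linkage tibble.
#' @export
write_linkage <- function(linkage, path) {
  readr::write_csv(dplyr::arrange(linkage, .data$insert_id, .data$barcode),
                   path)
  invisible(path)
}

#' @rdname write_linkage
#' @export
read_linkage <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    barcode = "c", insert_id = "c", reads = "i"
  ))
}
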