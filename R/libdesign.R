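#' Enumerate the 8x codon-pair repeat library
#'
#' All 4096 ordered pairs of the 64 codons, each repeated eight times to form
#' a 48-nt insert that is fused in frame between the reporter ORF halves.
#' Deterministic lexicographic order (codon 1 varying slowest).
#'
#' @return A tibble with one row per codon pair: `insert_id`, `codon1`,
#'   `codon2`, `hexamer` (6 nt), `insert_seq` (48 nt), `dipeptide` (two
#'   amino-acid letters, stop as `"*"`), and `has_stop`.
#' @export
#' @examples
#' lib <- codon_pair_library()
#' nrow(lib) # 4096
#' lib[lib$hexamer == "TTTAAG", "dipeptide"] # FK
codon_pair_library <- function() {
  codons <- codon_table()$codon
  grid <- tidyr::expand_grid(codon1 = codons, codon2 = codons)
  aa <- .codon_to_aa()
  grid |>
    dplyr::mutate(
      hexamer    = paste0(.data$codon1, .data$codon2),
      insert_seq = strrep(.data$hexamer, 8L),
      dipeptide  = paste0(aa[.data$codon1], aa[.data$codon2]),
      has_stop   = aa[.data$codon1] == "*" | aa[.data$codon2] == "*",
      insert_id  = paste0("pair_", .data$hexamer),
      .before    = 1
    ) |>
    dplyr::select(
      "insert_id", "codon1", "codon2", "hexamer",
      "insert_seq", "dipeptide", "has_stop"
    )
}

#' Rotate a codon-pair hexamer to a shifted reading frame
#'
#' Reading an 8x-repeated hexamer k nucleotides downstream is equivalent to
#' rotating the hexamer left by k. `rotate_hexamer()` performs the rotation
#' on hexamer strings; `rotate_frame()` applies it to a codon-pair library
#' tibble and recomputes the derived columns. Rotation by 3 swaps the two
#' codons; rotation is a group action modulo 6.
#'
#' @param hexamer Character vector of 6-nt hexamers.
#' @param pairs A codon-pair library tibble as from [codon_pair_library()].
#' @param k Integer shift in 0..5.
#' @return `rotate_hexamer()`: character vector of rotated hexamers.
#'   `rotate_frame()`: the library tibble with codons, hexamer, insert and
#'   dipeptide replaced by their frame-shifted images (original `insert_id`
#'   is retained so levels can be tracked across frames).
#' @export
#' @examples
#' rotate_hexamer("TTTAAG", 1) # "TTAAGT" (dipeptide LS)
#' rotate_hexamer("GTGAAA", 2) # "GAAAGT" (dipeptide ES)
rotate_hexamer <- function(hexamer, k) {
  stopifnot(is.numeric(k), length(k) == 1L)
  if (k < 0 || k > 5 || k != as.integer(k)) {
    stop("k must be an integer in 0..5")
  }
  stopifnot(all(nchar(hexamer) == 6L))
  if (k == 0) return(hexamer)
  paste0(substr(hexamer, k + 1L, 6L), substr(hexamer, 1L, k))
}

#' @rdname rotate_hexamer
#' @export
rotate_frame <- function(pairs, k) {
  stopifnot(is.data.frame(pairs), "hexamer" %in% names(pairs))
  aa <- .codon_to_aa()
  pairs |>
    dplyr::mutate(
      hexamer    = rotate_hexamer(.data$hexamer, k),
      codon1     = substr(.data$hexamer, 1L, 3L),
      codon2     = substr(.data$hexamer, 4L, 6L),
      insert_seq = strrep(.data$hexamer, 8L),
      dipeptide  = paste0(aa[.data$codon1], aa[.data$codon2]),
      has_stop   = aa[.data$codon1] == "*" | aa[.data$codon2] == "*"
    )
}

#' Generate random stop-free barcodes
#'
#' Barcodes are 24-nt strings of eight VNN repeats (V = A/C/G). Because all
#' three stop codons begin with T and every in-frame codon of the barcode
#' starts at a V position, no barcode contains an in-frame stop codon.
#' Draws are uniform over the 48^8 admissible barcodes using the current
#' RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param n Number of barcodes to draw.
#' @return Character vector of `n` 24-nt barcodes (not necessarily distinct).
#' @export
#' @examples
#' set.seed(1)
#' generate_barcodes(3)
generate_barcodes <- function(n) {
  stopifnot(is.numeric(n), n >= 0)
  n <- as.integer(n)
  if (n == 0L) return(character(0))
  v <- c("A", "C", "G")
  b <- c("A", "C", "G", "T")
  m <- matrix("", nrow = 24L, ncol = n)
  for (i in seq_len(24L)) {
    alphabet <- if ((i - 1L) %% 3L == 0L) v else b
    m[i, ] <- sample(alphabet, n, replace = TRUE)
  }
  apply(m, 2L, paste, collapse = "")
}

#' Default (FK)8 deep mutational scanning backbone
#'
#' Sixteen codons encoding (FK)8 with alternating synonymous codons
#' (TTT-AAA-TTC-AAG repeated) so the nucleotide sequence is not a pure
#' repeat.
#'
#' @return Character vector of 16 codons.
#' @export
fk8_backbone <- function() {
  rep(c("TTT", "AAA", "TTC", "AAG"), 4L)
}

#' Enumerate the (FK)8 deep mutational scanning library
#'
#' Each of the 16 codon positions of the backbone is substituted by all 64
#' codons, giving 1024 (position, codon) design entries. Entries whose codon
#' equals the backbone codon reproduce the backbone sequence, so the design
#' contains 1009 distinct nucleotide sequences (1008 single-codon mutants
#' plus the backbone itself).
#'
#' @param backbone Character vector of 16 codons (default [fk8_backbone()]).
#' @return A tibble with columns `variant_id`, `position` (1-16), `codon`,
#'   `insert_seq` (48 nt), `amino_acid`, `wt_amino_acid`, `is_wildtype_aa`,
#'   and `is_wildtype_codon`.
#' @export
#' @examples
#' dms <- dms_library()
#' nrow(dms) # 1024
dms_library <- function(backbone = fk8_backbone()) {
  stopifnot(is.character(backbone), length(backbone) == 16L,
            all(nchar(backbone) == 3L))
  aa <- .codon_to_aa()
  wt_aa <- unname(aa[backbone])
  codons <- codon_table()$codon
  grid <- tidyr::expand_grid(position = 1:16, codon = codons)
  seqs <- vapply(seq_len(nrow(grid)), function(i) {
    cods <- backbone
    cods[grid$position[i]] <- grid$codon[i]
    paste(cods, collapse = "")
  }, character(1))
  grid |>
    dplyr::mutate(
      variant_id        = sprintf("pos%02d_%s", .data$position, .data$codon),
      insert_seq        = seqs,
      amino_acid        = unname(aa[.data$codon]),
      wt_amino_acid     = wt_aa[.data$position],
      is_wildtype_aa    = .data$amino_acid == .data$wt_amino_acid,
      is_wildtype_codon = .data$codon == backbone[.data$position]
    ) |>
    dplyr::select(
      "variant_id", "position", "codon", "insert_seq",
      "amino_acid", "wt_amino_acid", "is_wildtype_aa", "is_wildtype_codon"
    )
}

#' Select endogenous ORF fragments for the reporter library
#'
#' Takes every 2nd gene in descending expression order and slices the
#' 1-based inclusive interval \[253, 300\] of its ORF (48 nt, codon-aligned).
#' ORFs shorter than 300 nt, or whose fragment contains a frame-0 stop codon
#' (which would truncate the reporter fusion), are dropped. Ranked ids with
#' no sequence are skipped and reported in the `skipped` attribute.
#'
#' @param orfs Named character vector (or tibble with `gene_id`, `seq`
#'   columns) of ORF sequences in frame 0 starting at ATG.
#' @param expression_rank Character vector of gene ids in descending order
#'   of RNA expression.
#' @param slice_start,slice_end 1-based inclusive fragment coordinates on
#'   the ORF (defaults 253 and 300).
#' @param every Take every `every`-th ranked gene (default 2).
#' @return A tibble `gene_id`, `fragment_seq`, `slice_start`, `slice_end`,
#'   with attribute `skipped` (ids missing from `orfs`) and `dropped`
#'   (ids excluded as too short or stop-containing).
#' @export
endogenous_fragments <- function(orfs, expression_rank,
                                 slice_start = 253L, slice_end = 300L,
                                 every = 2L) {
  if (is.data.frame(orfs)) {
    orfs <- stats::setNames(orfs$seq, orfs$gene_id)
  }
  stopifnot(is.character(orfs), !is.null(names(orfs)),
            slice_end > slice_start, every >= 1L)
  picked <- expression_rank[seq(1L, length(expression_rank), by = every)]
  missing <- picked[!picked %in% names(orfs)]
  if (length(missing)) {
    message(length(missing), " ranked gene(s) absent from ORF set; skipped")
  }
  picked <- picked[picked %in% names(orfs)]
  seqs <- orfs[picked]
  long_enough <- nchar(seqs) >= slice_end
  frag <- substr(seqs[long_enough], slice_start, slice_end)
  stop_free <- !has_frame0_stop(frag)
  dropped <- c(names(seqs)[!long_enough], names(frag)[!stop_free])
  out <- tibble::tibble(
    gene_id      = names(frag)[stop_free],
    fragment_seq = unname(frag[stop_free]),
    slice_start  = as.integer(slice_start),
    slice_end    = as.integer(slice_end)
  )
  attr(out, "skipped") <- missing
  attr(out, "dropped") <- dropped
  out
}

#' Read ORF sequences from a FASTA file
#'
#' @param path Path to a FASTA file of ORF sequences.
#' @return A tibble with columns `gene_id` and `seq`.
#' @export
read_orf_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    gene_id = sub("\\s.*$", "", names(x)),
    seq     = as.character(x)
  )
}

#' Write a library design to disk
#'
#' Writes a delimited design table and a matching FASTA of insert sequences.
#'
#' @param library A design tibble with `insert_seq` and an id column
#'   (`insert_id` or `variant_id`).
#' @param path Output path for the CSV table; the FASTA is written next to
#'   it with extension `.fasta`.
#' @return Invisibly, the CSV path.
#' @export
write_library <- function(library, path) {
  readr::write_csv(library, path)
  id_col <- intersect(c("insert_id", "variant_id", "gene_id"), names(library))[1]
  seqs <- Biostrings::DNAStringSet(library$insert_seq)
  names(seqs) <- library[[id_col]]
  Biostrings::writeXStringSet(seqs, sub("\\.[^.]+$", ".fasta", path))
  invisible(path)
}
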