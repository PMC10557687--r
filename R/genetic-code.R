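#' The standard genetic code as a tibble
#'
#' One row per codon of the standard (yeast nuclear) genetic code, with stop
#' codons rendered as `"*"`.
#'
#' @return A tibble with columns `codon`, `amino_acid` and `is_stop`,
#'   64 rows in lexicographic codon order.
#' @export
#' @examples
#' codon_table()
codon_table <- function() {
  code <- Biostrings::GENETIC_CODE
  tibble::tibble(
    codon      = names(code),
    amino_acid = unname(code),
    is_stop    = unname(code) == "*"
  ) |>
    dplyr::arrange(.data$codon)
}

# internal lookup vector codon -> amino acid
.codon_to_aa <- function() {
  code <- Biostrings::GENETIC_CODE
  stats::setNames(unname(code), names(code))
}

#' Translate codons or codon-aligned sequences
#'
#' `translate_codons()` maps a character vector of 3-nt codons to one-letter
#' amino acids (stop = `"*"`). `translate_seq()` translates frame 0 of each
#' nucleotide sequence whose length is a multiple of 3.
#'
#' @param codons Character vector of 3-letter codons over A/C/G/T.
#' @param seq Character vector of codon-aligned nucleotide sequences.
#' @return Character vector of amino acids (or peptide strings).
#' @export
#' @examples
#' translate_codons(c("TTT", "AAG", "TAA"))
#' translate_seq("TTTAAG")
translate_codons <- function(codons) {
  stopifnot(is.character(codons))
  bad <- nchar(codons) != 3L | grepl("[^ACGT]", codons)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(utils::head(codons[bad], 5), collapse = ", "))
  }
  unname(.codon_to_aa()[codons])
}

#' @rdname translate_codons
#' @export
translate_seq <- function(seq) {
  stopifnot(is.character(seq))
  if (any(nchar(seq) %% 3L != 0L)) {
    stop("sequence length must be a multiple of 3")
  }
  vapply(seq, function(s) {
    paste(translate_codons(split_codons(s)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Split a nucleotide sequence into codons
#'
#' @param seq A single codon-aligned nucleotide string.
#' @return Character vector of 3-nt codons.
#' @export
split_codons <- function(seq) {
  stopifnot(length(seq) == 1L, nchar(seq) %% 3L == 0L)
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# TRUE if frame 0 of `seq` contains a stop codon; vectorised
has_frame0_stop <- function(seq) {
  vapply(seq, function(s) {
    any(translate_codons(split_codons(s)) == "*")
  }, logical(1), USE.NAMES = FALSE)
}
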