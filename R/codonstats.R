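#' Positional mean mRNA levels per codon or amino acid
#'
#' For each codon (or amino acid) and each position of the codon pair,
#' computes the mean and standard deviation of insert levels over all
#' inserts carrying that unit at that position, then median-normalizes the
#' means across units within each position.
#'
#' @param levels Level table with `insert_id` and `level`.
#' @param library Codon-pair design from [codon_pair_library()].
#' @param unit `"codon"` or `"amino_acid"`.
#' @return A tibble (`unit`, `position`, `mean_level`, `sd_level`, `n`),
#'   with per-position median of `mean_level` equal to 0.
#' @export
positional_means <- function(levels, library,
                             unit = c("codon", "amino_acid")) {
  unit <- match.arg(unit)
  if (nrow(levels) == 0L) stop("empty level table")
  aa <- .codon_to_aa()
  joined <- dplyr::inner_join(
    levels[, c("insert_id", "level")], library, by = "insert_id"
  )
  u1 <- if (unit == "codon") joined$codon1 else unname(aa[joined$codon1])
  u2 <- if (unit == "codon") joined$codon2 else unname(aa[joined$codon2])
  long <- dplyr::bind_rows(
    tibble::tibble(unit = u1, position = 1L, level = joined$level),
    tibble::tibble(unit = u2, position = 2L, level = joined$level)
  )
  long |>
    dplyr::filter(is.finite(.data$level)) |>
    dplyr::group_by(.data$unit, .data$position) |>
    dplyr::summarise(
      mean_level = mean(.data$level),
      sd_level   = stats::sd(.data$level),
      n          = dplyr::n(),
      .groups    = "drop"
    ) |>
    dplyr::group_by(.data$position) |>
    dplyr::mutate(
      mean_level = .data$mean_level - stats::median(.data$mean_level)
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$position, .data$unit)
}

#' Codon stability coefficients
#'
#' The CSC of a codon is the Pearson correlation between the codon's
#' frequency in each insert (count among the 16 codons, divided by 16) and
#' the insert's mRNA level, across all inserts. Codons whose frequency is
#' constant across inserts are flagged rather than given a coefficient.
#'
#' @param levels Level table with `insert_id` and `level`.
#' @param library Design tibble with `insert_id` and `insert_seq` (any
#'   48-nt codon-aligned library).
#' @return A tibble (`codon`, `csc`, `n`, `constant`).
#' @export
compute_csc <- function(levels, library) {
  joined <- dplyr::inner_join(
    levels[, c("insert_id", "level")],
    library[, c("insert_id", "insert_seq")],
    by = "insert_id"
  ) |>
    dplyr::filter(is.finite(.data$level))
  codons <- codon_table()$codon
  cod_mat <- vapply(joined$insert_seq, split_codons,
                    character(nchar(joined$insert_seq[1]) %/% 3L))
  n_codons <- nrow(cod_mat)
  freq <- vapply(codons, function(cd) {
    colSums(cod_mat == cd) / n_codons
  }, numeric(ncol(cod_mat)))
  purrr::map_dfr(seq_along(codons), function(k) {
    f <- freq[, k]
    if (stats::var(f) == 0) {
      tibble::tibble(codon = codons[k], csc = NA_real_,
                     n = length(f), constant = TRUE)
    } else {
      tibble::tibble(codon = codons[k],
                     csc = stats::cor(f, joined$level),
                     n = length(f), constant = FALSE)
    }
  })
}

#' Mean mRNA level per dipeptide repeat
#'
#' Aggregates codon-pair insert levels over synonymous codon pairs encoding
#' the same dipeptide (stop rendered `"*"`). The default is an unweighted
#' mean over the synonymous insert estimates; `weight = "barcodes"` weights
#' by each insert's barcode count.
#'
#' @param levels Level table with `insert_id`, `level` (and `n_barcodes`
#'   for barcode weighting).
#' @param library Codon-pair design from [codon_pair_library()].
#' @param weight `"equal"` or `"barcodes"`.
#' @return A tibble over the full 21 x 21 grid (`aa1`, `aa2`, `dipeptide`,
#'   `level`, `sd`, `n`, `missing`), where `n` counts contributing inserts
#'   and cells with no surviving insert are flagged missing.
#' @export
dipeptide_levels <- function(levels, library, weight = c("equal", "barcodes")) {
  weight <- match.arg(weight)
  aa <- .codon_to_aa()
  joined <- dplyr::inner_join(
    levels, library[, c("insert_id", "codon1", "codon2")], by = "insert_id"
  ) |>
    dplyr::filter(is.finite(.data$level)) |>
    dplyr::mutate(aa1 = unname(aa[.data$codon1]),
                  aa2 = unname(aa[.data$codon2]))
  agg <- joined |>
    dplyr::group_by(.data$aa1, .data$aa2) |>
    dplyr::summarise(
      sd = stats::sd(.data$level),
      n = dplyr::n(),
      level = if (weight == "equal") mean(.data$level) else
        stats::weighted.mean(.data$level, .data$n_barcodes),
      .groups = "drop"
    ) |>
    dplyr::select("aa1", "aa2", "level", "sd", "n")
  aas <- sort(unique(unname(aa)))
  tidyr::expand_grid(aa1 = aas, aa2 = aas) |>
    dplyr::left_join(agg, by = c("aa1", "aa2")) |>
    dplyr::mutate(
      dipeptide = paste0(.data$aa1, .data$aa2),
      n = dplyr::coalesce(.data$n, 0L),
      missing = .data$n == 0L,
      .after = "aa2"
    )
}

#' Correlation of dipeptide levels between reading frames
#'
#' Compares dipeptide-level mRNA effects in the translated frame (frame 0)
#' with the effects of the dipeptides encoded k nucleotides downstream in
#' the repeated insert (the frame-k rotation of each hexamer). Dipeptides
#' containing a stop in either frame are excluded by default. A shift of 3
#' swaps the two codons, so it compares each dipeptide with its reversed
#' counterpart.
#'
#' @param levels Insert-level table (`insert_id`, `level`).
#' @param library Codon-pair design from [codon_pair_library()].
#' @param k Frame shift in 0..5.
#' @param exclude_stops Drop stop-containing dipeptides (default TRUE).
#' @return A one-row tibble (`k`, `r`, `n_dipeptides`).
#' @export
frame_shift_correlation <- function(levels, library, k,
                                    exclude_stops = TRUE) {
  f0 <- dipeptide_levels(levels, library) |>
    dplyr::filter(!.data$missing)
  fk <- dipeptide_levels(levels, rotate_frame(library, k)) |>
    dplyr::filter(!.data$missing)
  shared <- dplyr::inner_join(
    f0[, c("dipeptide", "level")], fk[, c("dipeptide", "level")],
    by = "dipeptide", suffix = c("_0", "_k")
  )
  if (exclude_stops) {
    shared <- dplyr::filter(shared, !grepl("\\*", .data$dipeptide))
  }
  if (nrow(shared) < 3L) stop("fewer than 3 shared dipeptides")
  tibble::tibble(
    k = as.integer(k),
    r = stats::cor(shared$level_0, shared$level_k),
    n_dipeptides = nrow(shared)
  )
}

#' Compare dipeptide mRNA levels between two genotypes or conditions
#'
#' Median-normalizes each level set within its own library, fits an
#' ordinary least-squares regression of the mutant (or condition) levels on
#' the baseline levels over shared dipeptides, and flags dipeptides whose
#' residual falls strictly below `residual_threshold` (preferentially
#' stabilized in the mutant relative to the trend) or whose level increase
#' exceeds `fc_threshold`-fold.
#'
#' @param baseline,mutant Dipeptide level tables from [dipeptide_levels()]
#'   (or any tibbles with `dipeptide` and `level`).
#' @param residual_threshold Residual flag cutoff in log2 units
#'   (default -2; strict inequality).
#' @param fc_threshold Fold-change flag cutoff on the linear scale
#'   (default 1.5; flag when mutant - baseline >= log2(fc_threshold)).
#' @param exclude_stops Drop stop-containing dipeptides (default TRUE).
#' @return A `genotype_comparison` object; see [tidy()] for the
#'   per-dipeptide table and [glance()] for the fit summary.
#' @export
compare_genotypes <- function(baseline, mutant, residual_threshold = -2,
                              fc_threshold = 1.5, exclude_stops = TRUE) {
  take <- function(x) {
    x <- x[is.finite(x$level), c("dipeptide", "level")]
    if (exclude_stops) x <- x[!grepl("\\*", x$dipeptide), ]
    x$level <- x$level - stats::median(x$level)
    x
  }
  shared <- dplyr::inner_join(take(baseline), take(mutant),
                              by = "dipeptide",
                              suffix = c("_baseline", "_mutant"))
  if (nrow(shared) < 3L) stop("fewer than 3 shared dipeptides")
  fit <- stats::lm(level_mutant ~ level_baseline, data = shared)
  data <- tibble::tibble(
    dipeptide = shared$dipeptide,
    baseline  = shared$level_baseline,
    mutant    = shared$level_mutant,
    residual  = unname(stats::residuals(fit)),
    flagged_residual = .data$residual < residual_threshold,
    flagged_fc = .data$mutant - .data$baseline >= log2(fc_threshold)
  )
  structure(
    list(data = data, fit = fit,
         residual_threshold = residual_threshold,
         fc_threshold = fc_threshold),
    class = "genotype_comparison"
  )
}

#' @export
print.genotype_comparison <- function(x, ...) {
  cf <- stats::coef(x$fit)
  cat("<genotype_comparison> ", nrow(x$data), " dipeptides; slope ",
      signif(cf[2], 3), ", intercept ", signif(cf[1], 3), "\n",
      sum(x$data$flagged_residual), " flagged by residual < ",
      x$residual_threshold, "; ", sum(x$data$flagged_fc),
      " with >= ", x$fc_threshold, "-fold increase\n", sep = "")
  invisible(x)
}

#' Correlate per-codon statistics with an external reference table
#'
#' Generic utility for comparing, e.g., codon-level mean levels or CSC
#' values against a user-supplied per-codon reference (no external values
#' are bundled).
#'
#' @param x Tibble with a `codon` column and one value column named in
#'   `value`.
#' @param reference Tibble with `codon` and a value column named in
#'   `ref_value`.
#' @param value,ref_value Column names to correlate.
#' @return A one-row tibble (`r`, `n`).
#' @export
correlate_with_reference <- function(x, reference, value = "csc",
                                     ref_value = "value") {
  shared <- dplyr::inner_join(
    x[, c("codon", value)], reference[, c("codon", ref_value)], by = "codon"
  )
  shared <- shared[stats::complete.cases(shared), ]
  if (nrow(shared) < 3L) stop("fewer than 3 shared codons")
  tibble::tibble(
    r = stats::cor(shared[[value]], shared[[ref_value]]),
    n = nrow(shared)
  )
}
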