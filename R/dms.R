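# Collapse the DMS design to distinguishable sequencing units: the 16
# entries whose mutant codon equals the backbone codon all share the
# backbone sequence and become one wild-type row.
dms_design_collapsed <- function(design) {
  wt_seq <- design$insert_seq[design$is_wildtype_codon][1]
  mut <- design[!design$is_wildtype_codon, ]
  dplyr::bind_rows(
    tibble::tibble(
      variant_id = "WT", position = NA_integer_, codon = NA_character_,
      insert_seq = wt_seq, amino_acid = NA_character_,
      wt_amino_acid = NA_character_, is_wildtype_aa = TRUE,
      is_wildtype_codon = TRUE
    ),
    mut
  )
}

#' Variant-level mRNA levels for a deep mutational scanning library
#'
#' Computes, per variant and biological replicate, the log2 ratio of summed
#' mRNA insert-UMI counts to summed gDNA insert-UMI counts, averages across
#' replicates, and subtracts the mean spike-in level so that levels are
#' comparable across genotypes. Variants absent from a replicate are
#' averaged over the replicates in which they appear and flagged via
#' `n_replicates`; the 16 design entries that reproduce the backbone
#' sequence are collapsed to a single wild-type row.
#'
#' @param counts Long tibble of UMI counts with columns `insert_seq`,
#'   `replicate`, `sample` (`"mrna"` or `"gdna"`), `count` — e.g. stacked
#'   outputs of [count_inserts()].
#' @param design DMS design from [dms_library()].
#' @param spikeins Optional character vector of spike-in insert sequences
#'   present in `counts`; their mean level is subtracted from all levels.
#' @return A tibble (`variant_id`, `position`, `codon`, `amino_acid`,
#'   `is_wildtype_aa`, `level`, `n_replicates`) with the per-replicate long
#'   table in attribute `per_replicate`.
#' @export
dms_levels <- function(counts, design, spikeins = NULL) {
  stopifnot(all(c("insert_seq", "replicate", "sample", "count")
                %in% names(counts)))
  wide <- counts |>
    tidyr::pivot_wider(
      id_cols = c("insert_seq", "replicate"),
      names_from = "sample", values_from = "count", values_fill = 0L
    )
  if (!all(c("mrna", "gdna") %in% names(wide))) {
    stop("counts must contain both 'mrna' and 'gdna' samples")
  }
  per_rep <- wide |>
    dplyr::mutate(level = ifelse(.data$mrna > 0 & .data$gdna > 0,
                                 log2(.data$mrna / .data$gdna),
                                 NA_real_)) |>
    dplyr::select("insert_seq", "replicate", "level")

  avg <- per_rep |>
    dplyr::filter(is.finite(.data$level)) |>
    dplyr::group_by(.data$insert_seq) |>
    dplyr::summarise(level = mean(.data$level),
                     n_replicates = dplyr::n(), .groups = "drop")

  shift <- 0
  if (!is.null(spikeins)) {
    sp <- avg$level[avg$insert_seq %in% spikeins]
    if (length(sp) == 0L) stop("no spike-in inserts found in counts")
    shift <- mean(sp)
  }
  collapsed <- dms_design_collapsed(design)
  out <- collapsed |>
    dplyr::inner_join(avg, by = "insert_seq") |>
    dplyr::mutate(level = .data$level - shift) |>
    dplyr::select("variant_id", "position", "codon", "amino_acid",
                  "is_wildtype_aa", "level", "n_replicates") |>
    dplyr::arrange(.data$variant_id)
  attr(out, "per_replicate") <- per_rep |>
    dplyr::inner_join(collapsed[, c("insert_seq", "variant_id")],
                      by = "insert_seq") |>
    dplyr::mutate(level = .data$level - shift) |>
    dplyr::select("variant_id", "replicate", "level")
  out
}

#' Position x amino-acid matrix of DMS levels
#'
#' Averages variant levels over synonymous codons per (position,
#' amino acid) cell; the collapsed wild-type variant contributes its level
#' to the backbone cell at every position. Wild-type amino acid cells are
#' marked (F at odd positions, K at even positions for the (FK)8 backbone).
#'
#' @param levels Output of [dms_levels()].
#' @param design DMS design from [dms_library()].
#' @return A long tibble (`position`, `amino_acid`, `level`, `n_codons`,
#'   `is_wildtype`), at most 16 x 21 rows.
#' @export
dms_matrix <- function(levels, design) {
  aa <- .codon_to_aa()
  wt_level <- levels$level[levels$variant_id == "WT"]
  per_variant <- design |>
    dplyr::left_join(
      levels[levels$variant_id != "WT", c("variant_id", "level")],
      by = "variant_id"
    ) |>
    dplyr::mutate(level = ifelse(.data$is_wildtype_codon,
                                 if (length(wt_level)) wt_level else NA_real_,
                                 .data$level))
  per_variant |>
    dplyr::filter(is.finite(.data$level)) |>
    dplyr::group_by(.data$position, .data$amino_acid) |>
    dplyr::summarise(
      level = mean(.data$level),
      n_codons = dplyr::n(),
      is_wildtype = .data$is_wildtype_aa[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$position, .data$amino_acid)
}

#' Position-wise rank-sum comparison of two genotypes
#'
#' For each position, compares the distributions of variant levels between
#' two genotypes with a two-sided Wilcoxon rank-sum test. The null
#' distribution is enumerated exactly when the combined sample size is at
#' most 20 and there are no ties; otherwise the normal approximation with
#' continuity correction is used. Stop-codon variants are excluded by
#' default (they confound NMD with RQC effects). Positions where the
#' distributions are not significantly different (p > alpha) are flagged.
#'
#' @param levels_a,levels_b Variant level tables from [dms_levels()]
#'   (need `position`, `amino_acid`, `level`).
#' @param alpha Significance level (default 0.01).
#' @param exclude_stops Drop stop-codon variants (default TRUE).
#' @return A tibble (`position`, `n_a`, `n_b`, `statistic`, `p_value`,
#'   `not_different`).
#' @export
positionwise_test <- function(levels_a, levels_b, alpha = 0.01,
                              exclude_stops = TRUE) {
  prep <- function(x) {
    x <- x[is.finite(x$level) & !is.na(x$position), ]
    if (exclude_stops) x <- x[x$amino_acid != "*", ]
    x[, c("position", "level")]
  }
  a <- prep(levels_a)
  b <- prep(levels_b)
  positions <- sort(unique(c(a$position, b$position)))
  purrr::map_dfr(positions, function(p) {
    xa <- a$level[a$position == p]
    xb <- b$level[b$position == p]
    if (length(xa) < 2L || length(xb) < 2L) {
      stop("position ", p, " has fewer than 2 variants in a group")
    }
    res <- ranksum_test(xa, xb)
    tibble::tibble(
      position = p, n_a = length(xa), n_b = length(xb),
      statistic = res$statistic, p_value = res$p_value,
      not_different = res$p_value > alpha
    )
  })
}

# two-sided Wilcoxon rank-sum; exact enumeration for combined n <= 20
# without ties, normal approximation with continuity and tie correction
# otherwise
ranksum_test <- function(x, y, exact_max = 20L) {
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y)) <= exact_max && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(res$statistic), p_value = res$p.value,
       exact = use_exact)
}

#' Pearson correlation between biological replicates
#'
#' @param levels Output of [dms_levels()] (uses its `per_replicate`
#'   attribute) or a long tibble (`variant_id`, `replicate`, `level`).
#' @param reps Which two replicates to compare (default the first two
#'   present).
#' @return A one-row tibble (`r`, `n`); `r` is `NA` with a warning when a
#'   replicate has zero variance.
#' @export
replicate_correlation <- function(levels, reps = NULL) {
  long <- attr(levels, "per_replicate")
  if (is.null(long)) long <- levels
  stopifnot(all(c("variant_id", "replicate", "level") %in% names(long)))
  if (is.null(reps)) reps <- sort(unique(long$replicate))[1:2]
  wide <- long |>
    dplyr::filter(.data$replicate %in% reps, is.finite(.data$level)) |>
    tidyr::pivot_wider(id_cols = "variant_id", names_from = "replicate",
                       values_from = "level") |>
    stats::na.omit()
  if (nrow(wide) < 3L) stop("fewer than 3 shared variants")
  v1 <- wide[[as.character(reps[1])]]
  v2 <- wide[[as.character(reps[2])]]
  if (stats::var(v1) == 0 || stats::var(v2) == 0) {
    warning("degenerate variance in a replicate; correlation undefined")
    return(tibble::tibble(r = NA_real_, n = nrow(wide)))
  }
  tibble::tibble(r = stats::cor(v1, v2), n = nrow(wide))
}
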