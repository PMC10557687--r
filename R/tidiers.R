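#' Tidy a genotype comparison
#'
#' @param x A `genotype_comparison` from [compare_genotypes()].
#' @param ... Unused.
#' @return One row per shared dipeptide: `dipeptide`, `baseline`, `mutant`,
#'   `residual`, `flagged_residual`, `flagged_fc`.
#' @export
tidy.genotype_comparison <- function(x, ...) {
  x$data
}

#' Summarise a genotype comparison fit
#'
#' @param x A `genotype_comparison` from [compare_genotypes()].
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `r`, `n_dipeptides`,
#'   `n_flagged_residual`, `n_flagged_fc`.
#' @export
glance.genotype_comparison <- function(x, ...) {
  cf <- stats::coef(x$fit)
  tibble::tibble(
    slope = unname(cf[2]),
    intercept = unname(cf[1]),
    r = stats::cor(x$data$baseline, x$data$mutant),
    n_dipeptides = nrow(x$data),
    n_flagged_residual = sum(x$data$flagged_residual),
    n_flagged_fc = sum(x$data$flagged_fc)
  )
}
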