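#' Plot positional codon or amino-acid mean levels
#'
#' Points with standard-deviation error bars, one panel per codon-pair
#' position, units ordered by their position-1 mean.
#'
#' @param pm Output of [positional_means()].
#' @return A ggplot object.
#' @export
plot_positional_means <- function(pm) {
  ord <- pm |>
    dplyr::filter(.data$position == 1L) |>
    dplyr::arrange(.data$mean_level)
  pm$unit <- factor(pm$unit, levels = ord$unit)
  ggplot2::ggplot(pm, ggplot2::aes(
    x = .data$unit, y = .data$mean_level,
    shape = factor(.data$position), colour = factor(.data$position)
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_level - .data$sd_level,
      ymax = .data$mean_level + .data$sd_level
    ), position = ggplot2::position_dodge(width = 0.5), linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "mean mRNA level (log2, median-normalized)",
                  shape = "pair position", colour = "pair position") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, size = 6))
}

#' Heatmap of dipeptide repeat mRNA levels
#'
#' @param dp Output of [dipeptide_levels()].
#' @return A ggplot object (amino acid 1 on x, amino acid 2 on y; missing
#'   cells grey).
#' @export
plot_dipeptide_matrix <- function(dp) {
  ggplot2::ggplot(dp, ggplot2::aes(
    x = .data$aa1, y = .data$aa2, fill = .data$level
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", na.value = "grey80") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "amino acid, position 1", y = "amino acid, position 2",
                  fill = "mRNA level\n(log2)") +
    ggplot2::theme_minimal()
}

#' Heatmap of the deep mutational scanning matrix
#'
#' Position along the repeat on x, mutant amino acid on y; wild-type cells
#' are marked with a cross.
#'
#' @param dm Output of [dms_matrix()].
#' @return A ggplot object.
#' @export
plot_dms_matrix <- function(dm) {
  ggplot2::ggplot(dm, ggplot2::aes(
    x = factor(.data$position), y = .data$amino_acid, fill = .data$level
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_point(data = dm[dm$is_wildtype, ], shape = 4) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", na.value = "grey80") +
    ggplot2::labs(x = "position in repeat", y = "mutant amino acid",
                  fill = "mRNA level\n(log2)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a genotype comparison
#'
#' Baseline levels on x, mutant levels on y, the OLS fit line, and
#' residual-flagged dipeptides highlighted and labelled.
#'
#' @param object A `genotype_comparison` from [compare_genotypes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genotype_comparison <- function(object, ...) {
  d <- object$data
  cf <- stats::coef(object$fit)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$baseline, y = .data$mutant)) +
    ggplot2::geom_abline(slope = cf[2], intercept = cf[1],
                         colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flagged_residual),
                        show.legend = FALSE) +
    ggplot2::geom_text(
      data = d[d$flagged_residual, ],
      ggplot2::aes(label = .data$dipeptide),
      vjust = -0.6, size = 3, colour = "#b2182b"
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "baseline mRNA level (log2)",
                  y = "mutant mRNA level (log2)") +
    ggplot2::theme_bw()
}
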