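#' Plot the gene-level density-slope association
#'
#' Representative points of the DNA-RNA vs RNA-protein density ridge with
#' the fitted least-squares line.
#'
#' @param object A `density_slope` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot density_slope
#' @export
autoplot.density_slope <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$dr, y = .data$rp)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "DNA–RNA correlation (rho)",
      y = "RNA–protein correlation (rho)",
      title = sprintf("Density-ridge association: slope = %.2f, rho = %.2f",
                      object$slope, object$rho)
    ) +
    ggplot2::theme_minimal()
}

#' Plot pathway-level regulation medians
#'
#' Each point is a pathway at its median DNA-RNA and RNA-protein
#' correlation; point size tracks pathway size.
#'
#' @param object A `pathway_regulation` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pathway_regulation
#' @export
autoplot.pathway_regulation <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$pathways,
                  ggplot2::aes(x = .data$median_dr_rho,
                               y = .data$median_rp_rho,
                               size = .data$n_genes)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6,
                         show.legend = FALSE) +
    ggplot2::labs(
      x = "pathway median DNA–RNA rho",
      y = "pathway median RNA–protein rho",
      size = "genes",
      title = sprintf("Pathway-level association: rho = %.2f (p = %.2g)",
                      g$spearman_rho, g$spearman_p)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of group-level compensation medians
#'
#' Tile plot of median compensation score by SCNA group (and any further
#' grouping columns present), with significance marks at the configured
#' FDR threshold.
#'
#' @param summary_table Tibble from [summarize_group_cs()].
#' @param fdr_threshold Significance mark threshold (default 0.005).
#' @return A ggplot.
#' @export
plot_compensation_summary <- function(summary_table, fdr_threshold = 0.005) {
  tb <- summary_table
  tb$row <- if ("tumor_type" %in% names(tb)) {
    paste(tb$layer, tb$tumor_type, sep = " / ")
  } else tb$layer
  tb$signif <- !is.na(tb$fdr) & tb$fdr < fdr_threshold & tb$median_cs > 0
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$scna_group, y = .data$row,
                                   fill = .data$median_cs)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$signif, "*", "")),
                       size = 5) +
    ggplot2::scale_fill_gradient2(low = "grey70", mid = "white",
                                  high = "cyan3", midpoint = 0) +
    ggplot2::labs(x = "SCNA group", y = NULL, fill = "median CS") +
    ggplot2::theme_minimal()
}

#' Bar chart of normalized enrichment scores
#'
#' @param object An enrichment tibble from [preranked_enrichment()].
#' @param fdr_threshold Sets at or above this FDR are greyed out
#'   (default 0.1).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scnareg_enrichment
#' @export
autoplot.scnareg_enrichment <- function(object, fdr_threshold = 0.1, ...) {
  tb <- tibble::as_tibble(object)
  tb$significant <- !is.na(tb$fdr) & tb$fdr < fdr_threshold
  tb$set <- stats::reorder(tb$set, tb$nes)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$nes, y = .data$set,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "normalized enrichment score", y = NULL,
                  fill = sprintf("FDR < %g", fdr_threshold)) +
    ggplot2::theme_minimal()
}
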