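#' Plot an abundance table
#'
#' Horizontal bar chart of relative abundance per reported genotype, on a
#' log10 axis so that a near-100% dominant genotype does not flatten the
#' minor-genotype tail.
#'
#' @param object An `abundance_table` from [quantify()].
#' @param all Include sub-threshold genotypes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot abundance_table
#' @export
autoplot.abundance_table <- function(object, all = FALSE, ...) {
  tab <- tidy(object, all = all)
  if (nrow(tab) == 0) abort("the abundance table has no rows to plot")
  tab$genotype <- factor(tab$genotype, levels = rev(tab$genotype))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$relative_abundance,
                                    y = .data$genotype)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "relative abundance (%, log scale)", y = NULL,
      title = sprintf("%s: %d genotype(s), %s assigned reads",
                      object$label, nrow(tab),
                      format(object$total_assigned, big.mark = ","))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a barcode window scan
#'
#' Polymorphism count per candidate window start, with the best windows
#' highlighted.
#'
#' @param windows Tibble from [scan_barcode_windows()].
#' @param top_n Number of top-ranked windows to highlight.
#' @return A ggplot object.
#' @export
plot_barcode_windows <- function(windows, top_n = 3) {
  best <- head(windows, top_n)
  ggplot2::ggplot(dplyr::arrange(windows, .data$window_start),
                  ggplot2::aes(x = .data$window_start,
                               y = .data$n_polymorphisms)) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::geom_point(data = best, colour = "firebrick") +
    ggplot2::labs(x = "window start (bp)",
                  y = "polymorphisms fully inside window") +
    ggplot2::theme_minimal()
}
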