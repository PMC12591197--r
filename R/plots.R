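# ggplot2 displays for the pipeline's result types.

#' Plot a composition estimate
#'
#' Stacked donor-proportion bar for a single estimate, in the style of a
#' per-tissue donor-contribution panel.
#'
#' @param object A `composition_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot composition_estimate
#' @export
autoplot.composition_estimate <- function(object, ...) {
  df <- tibble(
    donor = factor(c("O (L1)", "C (L2/L3)"), levels = c("O (L1)", "C (L2/L3)")),
    proportion = c(object$p_o, object$p_c)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = object$method, y = .data$proportion,
                                   fill = .data$donor)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "share of transcript pool",
                  fill = "donor (layer)",
                  title = sprintf("Donor composition: p_C = %.2f%%",
                                  100 * object$p_c)) +
    ggplot2::theme_minimal()
}

#' Plot donor composition across methods or tissues
#'
#' @param composition A tidy composition tibble (e.g. from
#'   [estimate_composition()] or bound across tissues), with columns
#'   `method`, `p_c`, and optional `ci_low`/`ci_high` and `tissue`.
#' @return A ggplot object with point estimates and any intervals.
#' @export
plot_composition <- function(composition) {
  check_columns(composition, c("method", "p_c"), "composition")
  x_var <- if ("tissue" %in% names(composition)) "tissue" else "method"
  p <- ggplot2::ggplot(composition,
                       ggplot2::aes(x = .data[[x_var]], y = .data$p_c,
                                    colour = .data$method)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.4), size = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(y = "donor-C (L2/L3) fraction of transcript pool",
                  x = NULL) +
    ggplot2::theme_minimal()
  if (all(c("ci_low", "ci_high") %in% names(composition))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.15, position = ggplot2::position_dodge(0.4), na.rm = TRUE)
  }
  p
}

#' Plot origin-category counts
#'
#' @param calls Classified calls from [classify_sites()] (or a summary
#'   from [tabulate_origins()]).
#' @return A ggplot bar chart of sites per donor-origin category.
#' @export
plot_origin_categories <- function(calls) {
  summary <- if ("n_sites" %in% names(calls)) calls else tabulate_origins(calls)
  summary$category <- factor(summary$category, levels = origin_levels)
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$category,
                                        y = .data$n_sites)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "donor-of-origin category", y = "diagnostic sites") +
    ggplot2::theme_minimal()
}

#' Plot per-gene donor-O allele frequencies by layer class
#'
#' @param gene_stats Per-gene tibble from [gene_layer_stats()].
#' @param bins Histogram bins (default 40).
#' @return A ggplot histogram of `f_o` coloured by `layer_class`.
#' @export
plot_gene_layers <- function(gene_stats, bins = 40) {
  check_columns(gene_stats, c("f_o", "layer_class"), "gene_stats")
  df <- dplyr::filter(gene_stats, !is.na(.data$f_o))
  df$layer_class <- factor(df$layer_class, levels = layer_levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f_o, fill = .data$layer_class)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::labs(x = "donor-O allele frequency (f_O)", y = "genes",
                  fill = "layer class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
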