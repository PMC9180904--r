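#' Plot a correlation network
#'
#' Draws the network with a force-directed (Fruchterman-Reingold) layout
#' weighted by |rho|: node colour by category, node size by degree, edge
#' colour by correlation sign and edge width by |rho| — mirroring the usual
#' Cytoscape presentation of these networks.
#'
#' @param object A `corr_network`.
#' @param seed Layout seed (layout is stochastic).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot corr_network
#' @export
autoplot.corr_network <- function(object, seed = 42, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes,
                         x = xy[, 1], y = xy[, 2],
                         degree = as.integer(igraph::degree(g)))
  edges <- dplyr::left_join(object$edges,
                            dplyr::select(nodes, "name", "x", "y"),
                            by = c(from = "name"))
  edges <- dplyr::left_join(edges,
                            dplyr::select(nodes, "name", xend = "x", yend = "y"),
                            by = c(to = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign,
                   linewidth = .data$weight),
      alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#c0392b", negative = "#2980b9"),
      name = "correlation") +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), guide = "none") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$category,
                   size = .data$degree),
      shape = 21, colour = "grey20") +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      size = 2.4, vjust = -1.2) +
    ggplot2::scale_size(range = c(2, 7), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "category")
}

#' Plot a network topology comparison
#'
#' Per-metric group means with SD error bars, annotated with the
#' Mann-Whitney p-value (and effect size r when significant).
#'
#' @param object A `network_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot network_comparison
#' @export
autoplot.network_comparison <- function(object, ...) {
  comp <- tidy.network_comparison(object)
  long <- tidyr::pivot_longer(
    comp, cols = c("mean_a", "mean_b"),
    names_to = "network", values_to = "mean")
  long$sd <- ifelse(long$network == "mean_a", comp$sd_a[match(long$metric, comp$metric)],
                    comp$sd_b[match(long$metric, comp$metric)])
  long$network <- ifelse(long$network == "mean_a", "A (reference)", "B")
  labels <- dplyr::mutate(
    comp,
    label = ifelse(is.na(.data$r),
                   sprintf("p = %.3g", .data$p_value),
                   sprintf("p = %.3g, r = %.2f", .data$p_value, .data$r)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$network, y = .data$mean)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$network), width = 0.6,
                      show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2) +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(x = 1.5, y = Inf, label = .data$label),
                       vjust = 1.5, size = 3, inherit.aes = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "metric value (mean ± SD)") +
    ggplot2::theme_minimal()
}

#' Plot a correlation matrix as a heatmap
#'
#' @param object A `correlation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlation_result
#' @export
autoplot.correlation_result <- function(object, ...) {
  long <- tidy.correlation_result(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$var1, y = .data$var2,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white",
                                  high = "#c0392b", limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
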