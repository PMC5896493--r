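# ggplot2 visualisations for the result objects.

#' Plot a haplotype network
#'
#' Draws the minimum spanning tree with node size proportional to total
#' abundance; edges are labelled with the number of base-pair differences and
#' novel haplotypes (absent from the reference set) are outlined dashed.
#'
#' @param object A `haplo_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.haplo_network <- function(object, ...) {
  nodes <- object$nodes
  g <- igraph::graph_from_data_frame(
    object$edges[, c("from", "to")], directed = FALSE,
    vertices = nodes$haplotype_id
  )
  set.seed(1L)  # layout only
  xy <- igraph::layout_with_fr(g)
  lay <- tibble::tibble(haplotype_id = igraph::V(g)$name,
                        x = xy[, 1], y = xy[, 2]) |>
    dplyr::left_join(nodes, by = "haplotype_id")
  ed <- object$edges |>
    dplyr::left_join(lay |> dplyr::select("haplotype_id", "x", "y"),
                     by = c(from = "haplotype_id")) |>
    dplyr::left_join(lay |> dplyr::select("haplotype_id", xend = "x", yend = "y"),
                     by = c(to = "haplotype_id"))
  lay$novel_shown <- dplyr::coalesce(lay$novel, FALSE)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey40"
    ) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$total,
                   shape = .data$novel_shown),
      colour = "steelblue"
    ) +
    ggplot2::geom_text(
      data = ed,
      ggplot2::aes(x = (.data$x + .data$xend) / 2, y = (.data$y + .data$yend) / 2,
                   label = .data$d),
      size = 3, vjust = -0.4
    ) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                name = "novel") +
    ggplot2::scale_size_area(name = "reads") +
    ggplot2::labs(title = sprintf("Haplotype network, OTU %s", object$otu_id)) +
    ggplot2::theme_void()
}

#' Plot per-OTU replicate consistency
#'
#' @param object A `replicate_r2` result.
#' @param ... Unused.
#' @return A ggplot object: adjusted R-squared per OTU with the mean marked.
#' @export
autoplot.replicate_r2 <- function(object, ...) {
  ggplot2::ggplot(object$per_otu,
                  ggplot2::aes(x = stats::reorder(.data$otu_id, .data$r2),
                               y = .data$r2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "adjusted R² between replicates",
                  title = sprintf("Replicate consistency (mean = %.3f, SD = %.3f)",
                                  object$mean, object$sd)) +
    ggplot2::theme_minimal()
}

#' Plot per-site haplotype frequencies for an OTU
#'
#' Stacked relative frequencies per site, the tabular counterpart of
#' haplotype pie-chart maps.
#'
#' @param table A `haplo_table`.
#' @param otu_id OTU to plot.
#' @return A ggplot object.
#' @export
plot_site_frequencies <- function(table, otu_id) {
  freqs <- site_frequencies(table, otu_id)
  ggplot2::ggplot(freqs, ggplot2::aes(x = .data$sample_id, y = .data$frequency,
                                      fill = .data$haplotype_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "site", y = "haplotype frequency", fill = "haplotype",
                  title = sprintf("Haplotype composition per site, OTU %s", otu_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
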