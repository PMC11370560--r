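#' Plot the phenotype clustering in principal-component space
#'
#' Scatter of animals on the first two behavioral PCs, colored by cluster
#' assignment.
#'
#' @param object A `sip_clustering` from [cluster_phenotypes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sip_clustering
#' @export
autoplot.sip_clustering <- function(object, ...) {
  df <- tibble::tibble(
    pc1 = object$pca$scores[, 1],
    pc2 = object$pca$scores[, 2],
    cluster = factor(object$clusters$cluster)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2,
                                   color = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$pca$ratios[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$pca$ratios[2]),
      color = "cluster"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Day-by-zeitgeber-time intake heat map
#'
#' Tile plot of a [heatmap_matrix()] table: one panel per group and
#' substance chamber, days on the y axis, ZT hour on the x axis.
#'
#' @param hm Long heat-map tibble (`group, chamber, day, zt, value`).
#' @return A ggplot object.
#' @export
plot_intake_heatmap <- function(hm) {
  ggplot2::ggplot(hm, ggplot2::aes(.data$zt, factor(.data$day),
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$group),
      cols = if ("chamber" %in% names(hm)) ggplot2::vars(.data$chamber)
    ) +
    ggplot2::scale_fill_viridis_c(name = "intake (ml/kg)") +
    ggplot2::labs(x = "zeitgeber time (h)", y = "day") +
    ggplot2::theme_minimal()
}

#' Plot the bootstrap cluster-stability table
#'
#' Mean agreement metric against candidate k, one line per metric.
#'
#' @param stability A [stability_table()] tibble.
#' @return A ggplot object.
#' @export
plot_stability <- function(stability) {
  long <- tidyr::pivot_longer(stability, -"k", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$k, .data$value,
                                     color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "k", y = "mean bootstrap agreement") +
    ggplot2::theme_minimal()
}
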