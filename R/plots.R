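#' Genotype heatmap in clustered order
#'
#' Tile plot of the dosage matrix with rows (individuals) and columns (loci)
#' in hierarchical-clustering order from [cluster_heatmap_order()].
#'
#' @param genotypes A tibble: `individual_id` plus dosage columns.
#' @param order Optional result of [cluster_heatmap_order()]; computed if
#'   missing.
#' @return A ggplot object.
#' @export
plot_genotype_heatmap <- function(genotypes, order = NULL) {
  if (is.null(order)) order <- cluster_heatmap_order(genotypes)
  long <- tidyr::pivot_longer(as_tibble(genotypes), -"individual_id",
                              names_to = "locus_id", values_to = "dosage")
  long$individual_id <- factor(long$individual_id, levels = order$row_order)
  long$locus_id <- factor(long$locus_id, levels = order$col_order)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$locus_id, y = .data$individual_id,
                                     fill = .data$dosage)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey90", high = "navy",
                                 na.value = "white", limits = c(0, 1),
                                 name = "MT dosage") +
    ggplot2::labs(x = "locus", y = "individual") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @method autoplot shape_pca
#' @export
autoplot.shape_pca <- function(object, group = NULL, pcs = c(1, 2), ...) {
  d <- object$scores
  d$PCa <- d[[paste0("PC", pcs[1])]]
  d$PCb <- d[[paste0("PC", pcs[2])]]
  if (!is.null(group)) d$group <- group
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PCa, y = .data$PCb)) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", pcs[1], 100 * object$variance_share[pcs[1]]),
      y = sprintf("PC%d (%.1f%%)", pcs[2], 100 * object$variance_share[pcs[2]])) +
    ggplot2::theme_minimal()
  if (is.null(group)) p + ggplot2::geom_point(alpha = 0.6)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.7)
}

#' @method autoplot grouped_glm_fit
#' @export
autoplot.grouped_glm_fit <- function(object, ...) {
  d <- object$fitted_odds
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$odds)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "covariate", y = "fitted odds") +
    ggplot2::theme_minimal()
}

#' Plot mean shapes per group
#'
#' @param shapes Output of [mean_shape()].
#' @return A ggplot object with one closed outline per group.
#' @export
plot_mean_shapes <- function(shapes) {
  ggplot2::ggplot(shapes, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$group)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
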