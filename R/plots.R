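# ggplot2 helpers for the main result types: PCA quadrant maps, temporal
# cluster profiles and z-score enrichment-profile heat maps.

#' @importFrom ggplot2 ggplot aes geom_point geom_hline geom_vline geom_tile
#'   geom_line labs scale_fill_gradient2 theme_minimal facet_wrap autoplot
NULL

#' @export
ggplot2::autoplot

#' Quadrant scatter plot of PCA scores
#'
#' @param object A `dgn_pca` object.
#' @param quadrants Optional tibble from [assign_quadrants()]; computed if
#'   missing.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dgn_pca
#' @export
autoplot.dgn_pca <- function(object, quadrants = NULL, ...) {
  qa <- quadrants %||% assign_quadrants(object)
  ggplot(qa, aes(x = .data$pc1, y = .data$pc2, colour = .data$quadrant)) +
    geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey50") +
    geom_vline(xintercept = 0, linewidth = 0.3, colour = "grey50") +
    geom_point(alpha = 0.6, size = 0.8) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$variance_explained[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$variance_explained[2]),
         colour = "Quadrant") +
    theme_minimal()
}

#' Mean temporal expression profile per cluster
#'
#' Averages the expression matrix over genes within each cluster and draws
#' one line per region across stages, faceted by cluster.
#'
#' @param matrix An `expr_matrix`.
#' @param clusters Tibble from [cut_tree()].
#' @return A ggplot object.
#' @export
plot_temporal_profiles <- function(matrix, clusters) {
  long <- as_tibble(matrix)
  long <- left_join(long, rename(clusters, gene = "item"), by = "gene")
  co <- expr_coords(matrix)
  prof <- long |>
    group_by(.data$cluster, .data$region, .data$stage) |>
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    mutate(stage = factor(.data$stage, levels = unique(co$stage)))
  ggplot(prof, aes(x = .data$stage, y = .data$value,
                   group = .data$region, colour = .data$region)) +
    geom_line(alpha = 0.7) +
    facet_wrap(~cluster) +
    labs(x = "Stage", y = "Mean log10 RPKM", colour = "Region") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Heat map of an enrichment z-score profile matrix
#'
#' Rows and columns are ordered by the UPGMA dendrograms of
#' [cluster_profiles()].
#'
#' @param z Z-score matrix from [inverse_normal_z()].
#' @param profile_clusters Optional output of [cluster_profiles()];
#'   computed if missing (requires >= 3 rows and >= 2 columns).
#' @return A ggplot object.
#' @export
plot_profile_heatmap <- function(z, profile_clusters = NULL) {
  pc <- profile_clusters %||% cluster_profiles(z)
  row_ord <- pc$row_tree$labels[pc$row_tree$order]
  col_ord <- pc$col_tree$labels[pc$col_tree$order]
  long <- as_tibble(z, rownames = "set_id") |>
    tidyr::pivot_longer(-"set_id", names_to = "entity", values_to = "z") |>
    mutate(set_id = factor(.data$set_id, levels = row_ord),
           entity = factor(.data$entity, levels = col_ord))
  ggplot(long, aes(x = .data$entity, y = .data$set_id, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    labs(x = NULL, y = NULL, fill = "z") +
    theme_minimal()
}
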