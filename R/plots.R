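# ggplot2 views of the main result types

#' Plot mean trait trajectories over time
#'
#' Mean value per genotype, treatment and day with standard-error
#' ribbons, one panel per genotype.
#'
#' @param df Long observation table (`genotype`, `treatment`, `das`,
#'   `trait`, `value`).
#' @param trait Trait to plot.
#' @param time Time column (`das`, or `aligned_das` after
#'   [time_shift()]).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(df, trait = "area_px", time = "das") {
  sub <- df[df$trait == trait, ]
  grouped <- dplyr::group_by(sub, .data$genotype, .data$treatment,
                             .data[[time]])
  summ <- dplyr::summarise(grouped, mean = mean(.data$value),
                           se = sd(.data$value) / sqrt(dplyr::n()),
                           .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data[[time]], .data$mean,
                                     colour = .data$treatment)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se,
                                      fill = .data$treatment),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$genotype)) +
    ggplot2::labs(x = "days after sowing", y = trait)
}

#' @describeIn build_phingerprint Heatmap of the phingerprint matrix
#'   with genotypes ordered by the dendrogram when a clustering is
#'   supplied.
#' @param object A `phingerprint` matrix.
#' @param clusters Optional [hcluster_phingerprint()] result.
#' @param ... Unused.
#' @method autoplot phingerprint
#' @export
autoplot.phingerprint <- function(object, clusters = NULL, ...) {
  m <- unclass(object)
  ord <- if (!is.null(clusters) && !is.null(clusters$hclust)) {
    clusters$hclust$labels[clusters$hclust$order]
  } else colnames(m)
  df <- tibble(feature = rownames(m)[row(m)],
               genotype = colnames(m)[col(m)],
               value = as.vector(m))
  df$genotype <- factor(df$genotype, levels = ord)
  df$feature <- factor(df$feature, levels = rev(rownames(m)))
  ggplot2::ggplot(df, ggplot2::aes(.data$genotype, .data$feature,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "value")
}

#' @describeIn hcluster_phingerprint Mean silhouette width against
#'   cluster count, with the chosen k marked.
#' @param object A `cold_clusters` result.
#' @param ... Unused.
#' @method autoplot cold_clusters
#' @export
autoplot.cold_clusters <- function(object, ...) {
  ggplot2::ggplot(object$silhouette,
                  ggplot2::aes(.data$k, .data$mean_silhouette)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2) +
    ggplot2::labs(x = "clusters (k)", y = "mean silhouette width")
}
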