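# broom-style tidiers for the package's fitted objects

#' Tidy a pixel classifier
#'
#' One row per class, channel and colour bin with the estimated density.
#'
#' @param x A [fit_pixel_classifier()] model.
#' @param ... Unused.
#' @return A tibble with columns `class`, `channel`, `bin`, `density`.
#' @method tidy pixel_classifier
#' @export
tidy.pixel_classifier <- function(x, ...) {
  purrr::map_dfr(x$classes, function(cl) {
    d <- x$densities[[cl]]
    tidyr::expand_grid(class = cl, channel = colnames(d), bin = 0:255) |>
      dplyr::mutate(density = as.vector(d))
  })
}

#' @rdname tidy.pixel_classifier
#' @method glance pixel_classifier
#' @export
glance.pixel_classifier <- function(x, ...) {
  tibble(n_classes = length(x$classes),
         n_train = sum(unlist(x$n_train)),
         colorspace = x$colorspace,
         mean_bandwidth = mean(x$bandwidths))
}

#' Tidy a pixel classification
#'
#' Class pixel counts and fractions for a classified image.
#'
#' @param x A [classify_pixels()] result.
#' @param ... Unused.
#' @method tidy pixel_classification
#' @export
tidy.pixel_classification <- function(x, ...) {
  counts <- tabulate(x$labels, nbins = length(x$classes))
  tibble(class = x$classes, n_pixels = counts,
         fraction = counts / length(x$labels))
}

#' Tidy a genotype clustering
#'
#' @param x A [hcluster_phingerprint()] result.
#' @param ... Unused.
#' @return One row per genotype with its cluster assignment.
#' @method tidy cold_clusters
#' @export
tidy.cold_clusters <- function(x, ...) {
  tibble(genotype = names(x$assignments),
         cluster = unname(x$assignments))
}

#' @rdname tidy.cold_clusters
#' @method glance cold_clusters
#' @export
glance.cold_clusters <- function(x, ...) {
  sil <- x$silhouette$mean_silhouette[x$silhouette$k == x$chosen_k]
  tibble(n_genotypes = length(x$assignments),
         chosen_k = x$chosen_k,
         mean_silhouette = if (length(sil)) sil else NA_real_,
         metric = x$metric, linkage = x$linkage)
}
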