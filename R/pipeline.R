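# end-to-end image measurement: classify -> clean -> rack exclusion ->
# split into pots -> trait extraction

#' Measure every plant in one plot image
#'
#' Runs the full segmentation and trait pipeline on a single RGB image:
#' naive Bayes pixel classification, mask cleanup (dilation + hole fill
#' defines the cleaned object region), rack-line detection, boundary
#' exclusion, splitting into pot strips, and trait extraction per pot.
#' Per-class pixel counts are the classified pixels inside the cleaned
#' region and above the boundary, so dilation never inflates area.
#'
#' @param image RGB array (H x W x 3, 0–255).
#' @param model A [fit_pixel_classifier()] model.
#' @param n_pots Number of pot strips (default 3).
#' @param dilate_radius Radius for [dilate_fill()].
#' @param search_fraction Passed to [detect_rack_line()].
#' @param boundary Optional known boundary row; skips rack detection.
#' @return A tibble with one row per pot (trait columns of
#'   [extract_traits()] plus `pot` and `rack_row`). Empty pots yield
#'   all-missing trait records.
#' @export
measure_image <- function(image, model, n_pots = 3, dilate_radius = 1,
                          search_fraction = 0.5, boundary = NULL) {
  cls <- classify_pixels(image, model)
  healthy <- cls$labels == match("healthy", cls$classes)
  necrotic <- cls$labels == match("necrotic", cls$classes)
  plant <- healthy | necrotic
  region <- if (any(plant)) dilate_fill(plant, dilate_radius) else plant
  rack <- boundary %||% detect_rack_line(image, search_fraction)
  masks <- apply_boundary(list(healthy = healthy & region,
                               necrotic = necrotic & region), rack)
  pots <- split_plants(masks, n_pots)
  res <- purrr::map_dfr(seq_len(nrow(pots)), function(i) {
    tr <- withCallingHandlers(
      extract_traits(pots$healthy[[i]], pots$necrotic[[i]]),
      coldpheno_empty_plant = function(w) invokeRestart("muffleWarning"))
    tr$pot <- pots$pot[i]
    tr
  })
  res$rack_row <- rack
  dplyr::relocate(res, "pot")
}

#' Measure a whole imaging experiment
#'
#' Applies [measure_image()] to every image of a metadata table and
#' merges the per-image results into one long-format-ready table keyed
#' by image, plot, pot, genotype, treatment, day and replicate —
#' the merged per-image CSV layout of the original pipeline.
#'
#' @param experiment Output of [generate_experiment()] in image mode
#'   (list with `images` and `meta`), or a directory written by it.
#' @param model A [fit_pixel_classifier()] model.
#' @param ... Passed to [measure_image()].
#' @return A wide tibble, one row per plant per image.
#' @export
measure_experiment <- function(experiment, model, ...) {
  if (is.character(experiment)) {
    meta <- as_tibble(read.csv(file.path(experiment, "metadata.csv")))
    images <- lapply(meta$image, function(nm) {
      round(png::readPNG(file.path(experiment, nm)) * 255)
    })
    names(images) <- meta$image
  } else {
    meta <- experiment$meta
    images <- lapply(experiment$images, function(x) x$image)
  }
  res <- purrr::map_dfr(seq_len(nrow(meta)), function(i) {
    tr <- measure_image(images[[meta$image[i]]], model, ...)
    dplyr::bind_cols(meta[rep(i, nrow(tr)), ], tr)
  })
  res$plant <- sprintf("%s_pot%d", res$plot, res$pot)
  dplyr::relocate(res, "plant")
}
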