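# synthetic plot-image rendering: blue backdrop, dark rack band, and up
# to `plants_per_plot` seedlings drawn as a stem rectangle plus a
# distance-filled elliptical leaf canopy in fixed vertical pot strips.

LABEL_BACKGROUND <- 0L
LABEL_RACK <- 1L
LABEL_HEALTHY <- 2L
LABEL_NECROTIC <- 3L

strip_bounds <- function(width, n_pots, pot) {
  sw <- width %/% n_pots
  x0 <- (pot - 1L) * sw + 1L
  x1 <- if (pot == n_pots) width else pot * sw
  c(x0, x1)
}

# paint one plant into the label matrix; returns the modified matrix.
# Pixel counts are exact: the canopy takes exactly the residual pixel
# budget in order of elliptical distance, so rendered area == target.
draw_plant <- function(labels, design, pot, area, height, width, necrotic) {
  img <- design$image
  H <- img$height
  b <- strip_bounds(img$width, design$plants_per_plot, pot)
  x0 <- b[1]; x1 <- b[2]
  A <- max(1L, round(area))
  h <- round(height)
  w <- round(width)
  if (h >= img$rack_top || w > (x1 - x0 + 1)) {
    abort(sprintf("plant (h=%d, w=%d) does not fit its pot strip", h, w),
          class = "coldpheno_image_overflow")
  }
  cx <- round((x0 + x1) / 2)
  yb <- img$rack_top - 1L          # stem base sits on the rack
  yt <- img$rack_top - h           # top of the plant

  stem_w <- max(1L, min(4L, A %/% h))
  sx <- cx - stem_w %/% 2
  stem_cols <- sx:(sx + stem_w - 1L)
  stem <- cbind(row = rep(yt:yb, times = stem_w),
                col = rep(stem_cols, each = h))
  if (nrow(stem) > A) stem <- stem[order(stem[, "row"])[seq_len(A)], , drop = FALSE]

  L <- A - nrow(stem)
  leaf <- NULL
  if (L > 0) {
    cy <- yt + round(0.25 * h)
    ax <- max((w - 1) / 2, 1)
    ay <- max(3, ceiling(1.1 * L / (pi * ax)))
    xs <- max(x0, cx - ceiling(ax)):min(x1, cx + ceiling(ax))
    ys <- max(yt, cy - ay):min(yb, cy + ay)
    cand <- expand.grid(row = ys, col = xs)
    d <- ((cand$col - cx) / ax)^2 + ((cand$row - cy) / ay)^2
    in_stem <- cand$row >= yt & cand$col %in% stem_cols
    cand <- cand[!in_stem, , drop = FALSE]
    d <- d[!in_stem]
    if (nrow(cand) < L) {
      abort("plant canopy does not fit its pot strip",
            class = "coldpheno_image_overflow")
    }
    ord <- order(d)
    leaf <- as.matrix(cand[ord[seq_len(L)], , drop = FALSE])
    leaf_d <- d[ord[seq_len(L)]]
  }

  px <- rbind(stem, leaf)
  labels[px] <- LABEL_HEALTHY

  n_nec <- min(nrow(px), round(necrotic))
  if (n_nec > 0) {
    # misclassified-stem baseline: lower stem first, then leaf tips
    stem_ord <- stem[order(-stem[, "row"]), , drop = FALSE]
    n_stem <- min(n_nec, nrow(stem_ord))
    nec <- stem_ord[seq_len(n_stem), , drop = FALSE]
    if (n_nec > n_stem) {
      tip <- leaf[order(-leaf_d)[seq_len(n_nec - n_stem)], , drop = FALSE]
      nec <- rbind(nec, tip)
    }
    labels[nec] <- LABEL_NECROTIC
  }
  labels
}

sample_layer <- function(n, mean_rgb, sd) {
  vapply(1:3, function(ch) rnorm(n, mean_rgb[ch], sd), numeric(n))
}

#' Render one synthetic plot image
#'
#' Draws up to `plants_per_plot` seedlings on a noisy blue backdrop with a
#' dark rack band whose top row is recorded as ground truth. Rendered
#' plant pixel counts equal the requested areas exactly; healthy pixels
#' are sampled around the configured green mean, necrotic pixels around
#' the brown mean. The same seed always yields a bitwise-identical image.
#'
#' @param plants Tibble of per-plant targets with columns `pot`,
#'   `area_px`, `height_px`, `width_px`, `necrotic_px`. Zero rows render
#'   pure background plus rack.
#' @param design A [experiment_design()] object (image geometry/colours).
#' @param seed Integer seed.
#' @return A list of class `cold_plot_image`: `image` (H x W x 3 array,
#'   0–255), `labels` (H x W integer matrix: 0 background, 1 rack,
#'   2 healthy, 3 necrotic), `rack_top` (row index), and `truth` (tibble
#'   of realized per-pot area/height/width/necrotic pixel counts).
#' @export
render_plot_image <- function(plants, design, seed = design$seed) {
  img <- design$image
  H <- img$height; W <- img$width
  if (nrow(plants) > design$plants_per_plot) {
    abort("more plants than pots in this design")
  }
  withr::with_seed(seed, {
    labels <- matrix(LABEL_BACKGROUND, H, W)
    labels[img$rack_top:H, ] <- LABEL_RACK
    for (i in seq_len(nrow(plants))) {
      labels <- draw_plant(labels, design, plants$pot[i], plants$area_px[i],
                           plants$height_px[i], plants$width_px[i],
                           plants$necrotic_px[i])
    }
    im <- array(0, dim = c(H, W, 3))
    flat <- matrix(im, ncol = 3)
    lab <- as.vector(labels)
    for (spec in list(
      list(LABEL_BACKGROUND, img$background_mean, img$background_sd),
      list(LABEL_RACK, img$rack_mean, img$rack_sd),
      list(LABEL_HEALTHY, img$healthy_mean, img$healthy_sd),
      list(LABEL_NECROTIC, img$necrotic_mean, img$necrotic_sd)
    )) {
      idx <- which(lab == spec[[1]])
      if (length(idx)) flat[idx, ] <- sample_layer(length(idx), spec[[2]], spec[[3]])
    }
    im <- array(pmin(255, pmax(0, round(flat))), dim = c(H, W, 3))
  })

  truth <- purrr::map_dfr(seq_len(nrow(plants)), function(i) {
    b <- strip_bounds(W, design$plants_per_plot, plants$pot[i])
    sub <- labels[, b[1]:b[2], drop = FALSE]
    plant <- sub == LABEL_HEALTHY | sub == LABEL_NECROTIC
    xy <- which(plant, arr.ind = TRUE)
    tibble(pot = plants$pot[i],
           area_px = nrow(xy),
           height_px = if (nrow(xy)) diff(range(xy[, 1])) + 1L else 0L,
           width_px = if (nrow(xy)) diff(range(xy[, 2])) + 1L else 0L,
           necrotic_px = sum(sub == LABEL_NECROTIC))
  })
  structure(list(image = im, labels = labels, rack_top = img$rack_top,
                 truth = truth),
            class = "cold_plot_image")
}

#' Generate a synthetic imaging experiment
#'
#' In image mode, renders one plot image per genotype, treatment,
#' replicate, plot and day, with per-plant targets taken from the
#' piecewise-linear growth model scaled by each plant's persistent size
#' factor. In table-only mode this is [simulate_experiment()]: the
#' ground-truth trait table is emitted directly, which is how the
#' statistical stages are exercised at scale.
#'
#' @param design A [experiment_design()] object. Image mode is intended
#'   for small designs (a few genotypes/replicates).
#' @param table_only If `TRUE`, return the plant-day trait table instead
#'   of images.
#' @param out_dir Optional directory: images and label maps are written
#'   as PNG, metadata and ground truth as CSV.
#' @return Table-only mode: a wide tibble (see [simulate_experiment()]).
#'   Image mode: a list with `images` (named list of
#'   [render_plot_image()] results), `meta` (tibble with columns
#'   `image, plot, genotype, treatment, das, replicate`) and `truth`
#'   (per plant per day realized counts).
#' @export
generate_experiment <- function(design, table_only = FALSE, out_dir = NULL) {
  if (isTRUE(table_only)) return(simulate_experiment(design))
  reg <- plant_registry(design)
  reg$plant_scale <- withr::with_seed(design$seed,
                                      pmax(0.3, rnorm(nrow(reg), 1,
                                                      design$plant_scale_sd)))
  plots <- unique(reg[c("plot", "genotype", "treatment", "replicate")])
  images <- list()
  meta <- list()
  truth <- list()
  k <- 0L
  for (p in seq_len(nrow(plots))) {
    gt <- design$genotypes[design$genotypes$genotype == plots$genotype[p], ]
    traj <- simulate_trajectory(gt, plots$treatment[p], design)
    pr <- reg[reg$plot == plots$plot[p], ]
    for (d in design$das) {
      k <- k + 1L
      tr <- traj[traj$das == d, ]
      plants <- tibble(
        pot = pr$pot,
        area_px = tr$area_px * pr$plant_scale,
        height_px = tr$height_px * pr$plant_scale,
        width_px = tr$width_px * pr$plant_scale,
        necrotic_px = tr$necrotic_px * pr$plant_scale
      )
      ren <- render_plot_image(plants, design, seed = sub_seed(design$seed, k))
      name <- sprintf("%s_das%02d.png", plots$plot[p], d)
      images[[name]] <- ren
      meta[[k]] <- tibble(image = name, plot = plots$plot[p],
                          genotype = plots$genotype[p],
                          treatment = plots$treatment[p], das = d,
                          replicate = plots$replicate[p])
      truth[[k]] <- dplyr::mutate(ren$truth, image = name,
                                  plot = plots$plot[p], das = d,
                                  genotype = plots$genotype[p],
                                  treatment = plots$treatment[p],
                                  replicate = plots$replicate[p])
    }
  }
  out <- list(images = images, meta = dplyr::bind_rows(meta),
              truth = dplyr::bind_rows(truth))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels"), showWarnings = FALSE)
    for (name in names(out$images)) {
      png::writePNG(out$images[[name]]$image / 255,
                    file.path(out_dir, name))
      png::writePNG(out$images[[name]]$labels / 255,
                    file.path(out_dir, "labels", name))
    }
    write.csv(out$meta, file.path(out_dir, "metadata.csv"),
              row.names = FALSE)
    write.csv(out$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  out
}

#' Sample labeled training pixels from ground truth
#'
#' Draws `n_per_class` pixels per class uniformly from the ground-truth
#' label maps of one or more rendered images. Rack pixels are pooled into
#' the background class (the classifier treats the backdrop, rack and
#' soil generically as non-plant).
#'
#' @param images A [render_plot_image()] result, a list of them, or the
#'   output of [generate_experiment()] in image mode.
#' @param n_per_class Pixels to sample per class.
#' @param seed Integer seed.
#' @return A tibble with columns `class`, `r`, `g`, `b` and exactly
#'   `3 * n_per_class` rows.
#' @export
sample_training_pixels <- function(images, n_per_class = 1000, seed = 1) {
  if (inherits(images, "cold_plot_image")) images <- list(images)
  if (!is.null(images$images)) images <- images$images
  assert_count(n_per_class, "n_per_class")
  class_labels <- list(background = c(LABEL_BACKGROUND, LABEL_RACK),
                       healthy = LABEL_HEALTHY, necrotic = LABEL_NECROTIC)
  withr::with_seed(seed, {
    rows <- purrr::map(names(class_labels), function(cl) {
      pools <- purrr::map(images, function(im) {
        which(im$labels %in% class_labels[[cl]])
      })
      counts <- lengths(pools)
      if (sum(counts) == 0) {
        abort(sprintf("class '%s' absent from ground truth", cl),
              class = "coldpheno_insufficient_training_data")
      }
      img_idx <- sample.int(length(images), n_per_class, replace = TRUE,
                            prob = counts)
      purrr::map_dfr(seq_len(n_per_class), function(j) {
        im <- images[[img_idx[j]]]
        lin <- sample(pools[[img_idx[j]]], 1L)
        n <- nrow(im$labels)
        row <- (lin - 1L) %% n + 1L
        col <- (lin - 1L) %/% n + 1L
        tibble(class = cl, r = im$image[row, col, 1],
               g = im$image[row, col, 2], b = im$image[row, col, 3])
      })
    })
  })
  dplyr::bind_rows(rows)
}
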