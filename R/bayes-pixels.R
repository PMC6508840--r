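# Naive Bayes per-channel colour classifier. Each class gets one
# Gaussian-kernel density per colour channel, evaluated on the integer
# grid 0..255; pixels are scored assuming channel independence.

DENSITY_FLOOR <- 1e-9
CLASS_ORDER <- c("background", "healthy", "necrotic")

order_classes <- function(classes) {
  known <- intersect(CLASS_ORDER, classes)
  c(known, sort(setdiff(classes, CLASS_ORDER)))
}

# KDE evaluated on bins 0..255, floored and renormalized to sum to 1
channel_density <- function(values, bandwidth) {
  d <- rowSums(dnorm(outer(0:255, values, "-"), sd = bandwidth)) /
    length(values)
  d <- d + DENSITY_FLOOR
  d / sum(d)
}

rgb_to_hsv255 <- function(r, g, b) {
  h <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  round(t(h) * 255)
}

#' Train the naive Bayes pixel classifier
#'
#' Estimates, for every class and colour channel, a Gaussian-kernel
#' density over the integer bins 0..255 from a labeled training table,
#' plus class priors. Classification multiplies the three per-channel
#' densities (channel independence) with the prior.
#'
#' The default bandwidth is Silverman's rule per class and channel
#' (never below 0.5 bins); a density floor of `1e-9` per bin keeps
#' unseen colours from producing zero posterior everywhere. Priors are
#' uniform unless supplied.
#'
#' @param pixels Tibble/data frame with columns `class`, `r`, `g`, `b`
#'   (channel values 0–255); at least two classes with >= 30 rows each.
#' @param bandwidth Optional fixed kernel bandwidth (positive).
#' @param priors Optional named class priors (normalized internally).
#' @param colorspace `"rgb"` (default, the space of the training table)
#'   or `"hsv"` (training values and images are converted before density
#'   estimation).
#' @return An object of class `pixel_classifier`.
#' @export
fit_pixel_classifier <- function(pixels, bandwidth = NULL, priors = NULL,
                                 colorspace = c("rgb", "hsv")) {
  colorspace <- match.arg(colorspace)
  pixels <- as.data.frame(pixels)
  names(pixels) <- tolower(names(pixels))
  stopifnot(all(c("class", "r", "g", "b") %in% names(pixels)))
  chan <- as.matrix(pixels[c("r", "g", "b")])
  if (any(chan < 0 | chan > 255)) {
    abort("channel values must be in [0, 255]",
          class = "coldpheno_invalid_parameter")
  }
  if (!is.null(bandwidth) && bandwidth <= 0) {
    abort("`bandwidth` must be positive",
          class = "coldpheno_invalid_parameter")
  }
  classes <- order_classes(unique(pixels$class))
  if (length(classes) < 2) abort("at least two classes are required",
                                 class = "coldpheno_insufficient_training_data")
  counts <- table(pixels$class)
  if (any(counts < 30)) {
    abort(sprintf("classes with < 30 training pixels: %s",
                  paste(names(counts)[counts < 30], collapse = ", ")),
          class = "coldpheno_insufficient_training_data")
  }
  if (colorspace == "hsv") chan <- rgb_to_hsv255(chan[, 1], chan[, 2], chan[, 3])

  densities <- list()
  bandwidths <- matrix(NA_real_, length(classes), 3,
                       dimnames = list(classes, c("r", "g", "b")))
  for (cl in classes) {
    v <- chan[pixels$class == cl, , drop = FALSE]
    dens <- matrix(NA_real_, 256, 3, dimnames = list(NULL, c("r", "g", "b")))
    for (ch in 1:3) {
      h <- bandwidth %||% max(bw.nrd0(v[, ch]), 0.5)
      bandwidths[cl, ch] <- h
      dens[, ch] <- channel_density(v[, ch], h)
    }
    densities[[cl]] <- dens
  }
  if (is.null(priors)) {
    priors <- setNames(rep(1 / length(classes), length(classes)), classes)
  } else {
    priors <- priors[classes] / sum(priors[classes])
  }
  structure(list(classes = classes, densities = densities, priors = priors,
                 bandwidths = bandwidths, colorspace = colorspace,
                 n_train = as.list(counts[classes])),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat("<pixel_classifier>", x$colorspace, "space;",
      paste(sprintf("%s (n=%s)", x$classes, unlist(x$n_train)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Classify every pixel of an RGB image
#'
#' Per pixel, class posteriors are proportional to prior times the
#' product of the three per-channel densities; the label is the
#' maximum-posterior class, with exact ties broken by the fixed class
#' order background > healthy > necrotic. Pixels whose likelihood sits at
#' the density floor for every class are assigned background and flagged.
#'
#' @param image An 8-bit RGB array (H x W x 3, values 0–255).
#' @param model A [fit_pixel_classifier()] model.
#' @return A list of class `pixel_classification`: `labels` (H x W
#'   integer matrix indexing into `classes`), `classes`, `posterior`
#'   (H x W x n_classes array summing to 1 per pixel) and `flagged`
#'   (logical matrix).
#' @export
classify_pixels <- function(image, model) {
  assert_rgb_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  chan <- matrix(pmin(255, pmax(0, round(as.vector(image)))), ncol = 3)
  if (model$colorspace == "hsv") {
    chan <- rgb_to_hsv255(chan[, 1], chan[, 2], chan[, 3])
  }
  K <- length(model$classes)
  loglik <- matrix(0, nrow(chan), K)
  for (k in seq_len(K)) {
    d <- model$densities[[model$classes[k]]]
    loglik[, k] <- log(d[chan[, 1] + 1L, 1]) + log(d[chan[, 2] + 1L, 2]) +
      log(d[chan[, 3] + 1L, 3])
  }
  logpost <- sweep(loglik, 2, log(model$priors), "+")
  m <- apply(logpost, 1, max)
  post <- exp(logpost - m)
  post <- post / rowSums(post)
  labels <- max.col(post, ties.method = "first")

  # effectively unseen colour: every class has all three channel
  # densities within an order of magnitude of the floor
  flagged <- apply(loglik, 1, max) <= 3 * log(10 * DENSITY_FLOOR)
  bg <- match("background", model$classes)
  if (!is.na(bg)) labels[flagged] <- bg

  structure(list(
    labels = matrix(labels, H, W),
    classes = model$classes,
    posterior = array(post, dim = c(H, W, K),
                      dimnames = list(NULL, NULL, model$classes)),
    flagged = matrix(flagged, H, W)
  ), class = "pixel_classification")
}

FALSE_COLOR_HEALTHY <- c(0, 160, 0)
FALSE_COLOR_NECROTIC <- c(139, 69, 19)

#' False-colour an image from its pixel labels
#'
#' Healthy pixels become solid green, necrotic pixels solid brown;
#' everything else is left unchanged.
#'
#' @param image RGB array (H x W x 3).
#' @param labels H x W integer label matrix (a `pixel_classification`
#'   can be passed directly).
#' @param classes Class names matching the label codes (taken from a
#'   `pixel_classification` automatically).
#' @return An RGB array of the input dimensions.
#' @export
false_color <- function(image, labels, classes = NULL) {
  assert_rgb_image(image)
  if (inherits(labels, "pixel_classification")) {
    classes <- labels$classes
    labels <- labels$labels
  }
  if (!all(dim(labels) == dim(image)[1:2])) {
    abort("label map dimensions must match the image")
  }
  classes <- classes %||% CLASS_ORDER
  out <- image
  for (spec in list(list("healthy", FALSE_COLOR_HEALTHY),
                    list("necrotic", FALSE_COLOR_NECROTIC))) {
    code <- match(spec[[1]], classes)
    if (is.na(code)) next
    idx <- which(labels == code)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[idx] <- spec[[2]][ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' Read a labeled-pixel training table
#'
#' Accepts comma- or tab-delimited text with a `class,r,g,b` header.
#'
#' @param path File path.
#' @return A tibble with columns `class`, `r`, `g`, `b`.
#' @export
read_pixel_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  as_tibble(df[c("class", "r", "g", "b")])
}

#' Serialize / restore a trained classifier
#'
#' The model is written as a single portable JSON file holding the bin
#' grid densities, priors, bandwidths and colour-space tag.
#'
#' @param model A `pixel_classifier`.
#' @param path Output path.
#' @export
write_pixel_classifier <- function(model, path) {
  jsonlite::write_json(list(
    classes = model$classes,
    colorspace = model$colorspace,
    priors = as.list(model$priors),
    bandwidths = as.data.frame(model$bandwidths),
    n_train = model$n_train,
    densities = purrr::map(model$densities, as.data.frame)
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pixel_classifier
#' @export
read_pixel_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    classes = x$classes,
    densities = purrr::map(x$densities, as.matrix)[x$classes],
    priors = unlist(x$priors)[x$classes],
    bandwidths = as.matrix(x$bandwidths),
    colorspace = x$colorspace,
    n_train = as.list(unlist(x$n_train))
  ), class = "pixel_classifier")
}
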