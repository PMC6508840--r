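# mask cleanup and rack exclusion: dilation + hole filling, detection of
# the rack's top edge, boundary exclusion, and fixed-strip plant splitting

#' Dilate a binary mask and fill its holes
#'
#' Morphological dilation with a square structuring element of the given
#' radius, followed by hole filling (background components not connected
#' to the image border are absorbed). The output always contains the
#' input.
#'
#' @param mask Binary matrix (logical or 0/1).
#' @param radius Positive integer radius; the structuring element is a
#'   `(2 * radius + 1)`-pixel square.
#' @return A logical matrix of the input dimensions.
#' @export
dilate_fill <- function(mask, radius = 1) {
  mask <- as_binary_mask(mask)
  assert_count(radius, "radius")
  if (!any(mask)) return(mask)
  kern <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "box")
  out <- EBImage::fillHull(EBImage::dilate(mask * 1, kern))
  matrix(as.logical(out), nrow(mask), ncol(mask))
}

#' Detect the top edge of the pot rack
#'
#' Scores each row in the bottom `search_fraction` of the grayscale image
#' by the mean absolute vertical intensity step from the row above, and
#' returns the row maximizing it — the transition from backdrop to the
#' dark rack band.
#'
#' @param image RGB array (H x W x 3, 0–255), taller than 10 rows.
#' @param search_fraction Fraction of rows, from the bottom, to search.
#' @param min_score Minimum winning gradient score (intensity units);
#'   below it the image is considered rack-free and an error of class
#'   `coldpheno_rack_not_found` is thrown.
#' @return The row index of the rack's top edge.
#' @export
detect_rack_line <- function(image, search_fraction = 0.5, min_score = 5) {
  assert_rgb_image(image)
  H <- dim(image)[1]
  if (H <= 10) abort("image must be taller than 10 rows")
  if (search_fraction <= 0 || search_fraction > 1) {
    abort("`search_fraction` must be in (0, 1]",
          class = "coldpheno_invalid_parameter")
  }
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  score <- rowMeans(abs(gray[2:H, , drop = FALSE] -
                          gray[1:(H - 1), , drop = FALSE]))
  rows <- 2:H                      # score[i-1] belongs to row i
  keep <- rows > H - floor(search_fraction * H)
  rows <- rows[keep]; score <- score[keep]
  if (max(score) < min_score) {
    abort("no rack-like edge found in the search region",
          class = "coldpheno_rack_not_found")
  }
  rows[which.max(score)]
}

#' Exclude all mask pixels at or below a boundary row
#'
#' The plant region is the half-open `y < boundary`: pixels at the
#' boundary row itself are removed. Idempotent.
#'
#' @param masks A binary matrix or a (possibly nested) named list of
#'   binary matrices.
#' @param boundary Row index (1 to image height + 1).
#' @return Masks of the same shape with rows `>= boundary` cleared.
#' @export
apply_boundary <- function(masks, boundary) {
  clear <- function(m) {
    m <- as_binary_mask(m)
    if (boundary <= nrow(m)) m[boundary:nrow(m), ] <- FALSE
    m
  }
  if (is.matrix(masks)) return(clear(masks))
  lapply(masks, apply_boundary, boundary = boundary)
}

#' Split a plot mask into per-plant masks by pot strip
#'
#' Each plant pixel is assigned to the fixed equal-width vertical strip
#' containing it (the rightmost strip absorbs any remainder), matching
#' the fixed pot positions of the imaging rack. A leaf crossing a strip
#' boundary is split between pots; total pixel count is conserved.
#'
#' @param masks Named list of binary matrices (e.g. `healthy`,
#'   `necrotic`) or a single matrix (returned as the `plant` element).
#' @param n_pots Number of pots (strips).
#' @return A tibble with one row per pot: `pot`, `empty` (no plant
#'   pixels in the strip), and one list-column of masks per input mask.
#' @export
split_plants <- function(masks, n_pots) {
  assert_count(n_pots, "n_pots")
  if (is.matrix(masks)) masks <- list(plant = masks)
  masks <- lapply(masks, as_binary_mask)
  W <- ncol(masks[[1]])
  out <- purrr::map_dfr(seq_len(n_pots), function(pot) {
    b <- strip_bounds(W, n_pots, pot)
    cropped <- lapply(masks, function(m) {
      s <- m
      s[, setdiff(seq_len(W), b[1]:b[2])] <- FALSE
      s
    })
    row <- tibble(pot = pot,
                  empty = !any(Reduce(`|`, cropped)))
    for (nm in names(cropped)) row[[nm]] <- list(cropped[[nm]])
    row
  })
  out
}
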