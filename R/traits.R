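# morphological trait extraction from per-plant binary masks.
# Coordinates are pixel centers: x = column, y = row, origin top-left.

#' Names of the sixteen morphological traits
#' @return Character vector, in canonical output order.
#' @export
morph_trait_names <- function() {
  c("height_px", "width_px", "area_px", "perimeter_px", "hull_area_px",
    "hull_vertices", "longest_axis_px", "solidity",
    "ellipse_center_x_px", "ellipse_center_y_px", "ellipse_major_px",
    "ellipse_minor_px", "ellipse_angle_deg", "eccentricity",
    "center_of_mass_x_px", "center_of_mass_y_px")
}

# remove collinear vertices from a closed polygon (matrix of x,y rows)
drop_collinear <- function(v) {
  n <- nrow(v)
  if (n < 3) return(v)
  keep <- vapply(seq_len(n), function(i) {
    a <- v[if (i == 1) n else i - 1, ]
    b <- v[i, ]
    c <- v[if (i == n) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    abs(cross) > 1e-9
  }, logical(1))
  v[keep, , drop = FALSE]
}

shoelace <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# lattice points on the hull boundary (for Pick's theorem)
boundary_lattice_points <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  dx <- abs(v[j, 1] - v[, 1])
  dy <- abs(v[j, 2] - v[, 2])
  sum(mapply(function(a, b) {
    while (b != 0) { t <- b; b <- a %% b; a <- t }
    a
  }, round(dx), round(dy)))
}

#' Convex-hull metrics of a pixel set
#'
#' The hull is taken over pixel centers, with collinear points removed
#' from the vertex list. `hull_area` is the number of pixel centers on
#' or inside the hull polygon (via Pick's theorem from the shoelace
#' area), so a filled convex shape has `hull_area` equal to its pixel
#' count and solidity 1. Degenerate (collinear) sets use the pixel count
#' as hull area. `longest_axis` is the maximum pairwise distance among
#' hull vertices.
#'
#' @param xy Matrix with columns `x`, `y` (pixel centers), >= 1 row.
#' @return A one-row tibble: `hull_area_px`, `hull_vertices`,
#'   `longest_axis_px`.
#' @export
convex_hull_metrics <- function(xy) {
  xy <- unique(xy[, 1:2, drop = FALSE])
  n <- nrow(xy)
  if (n == 0) abort("at least one pixel is required")
  if (n == 1) {
    return(tibble(hull_area_px = 1, hull_vertices = 1L, longest_axis_px = 0))
  }
  ctr <- sweep(xy, 2, colMeans(xy))
  degenerate <- n == 2 ||
    abs(det(crossprod(ctr))) < 1e-9 * (sum(ctr^2) / n + 1)^2
  if (degenerate) {
    d <- as.matrix(stats::dist(xy))
    return(tibble(hull_area_px = n, hull_vertices = 2L,
                  longest_axis_px = max(d)))
  }
  h <- grDevices::chull(xy)
  v <- drop_collinear(xy[h, , drop = FALSE])
  area <- shoelace(v)
  b <- boundary_lattice_points(v)
  tibble(hull_area_px = area + b / 2 + 1,
         hull_vertices = nrow(v),
         longest_axis_px = max(stats::dist(v)))
}

#' Image-moments ellipse of a pixel set
#'
#' The ellipse whose second central moments match the pixel
#' coordinates': full axis lengths are `4 * sqrt(eigenvalue)` of the
#' coordinate covariance (so a rasterized disk's major axis is its
#' diameter), the angle is the major eigenvector's orientation from the
#' +x axis mapped to \[0, 180), and eccentricity is
#' `sqrt(1 - (minor/major)^2)`. Degenerate (collinear) sets report a
#' zero minor axis and missing eccentricity with a
#' `coldpheno_degenerate_ellipse` warning.
#'
#' @param xy Matrix with columns `x`, `y` (pixel centers).
#' @return A one-row tibble: `ellipse_center_x_px`,
#'   `ellipse_center_y_px`, `ellipse_major_px`, `ellipse_minor_px`,
#'   `ellipse_angle_deg`, `eccentricity`.
#' @export
ellipse_moments <- function(xy) {
  xy <- xy[, 1:2, drop = FALSE]
  n <- nrow(xy)
  if (n == 0) abort("at least one pixel is required")
  mu <- unname(colMeans(xy))
  ctr <- sweep(xy, 2, mu)
  cov <- crossprod(ctr) / n              # population moments
  e <- eigen(cov, symmetric = TRUE)
  major <- 4 * sqrt(max(e$values[1], 0))
  minor <- 4 * sqrt(max(e$values[2], 0))
  vec <- e$vectors[, 1]
  angle <- (atan2(vec[2], vec[1]) * 180 / pi) %% 180
  degenerate <- n < 3 || e$values[2] <= 1e-9 * max(e$values[1], 1)
  if (degenerate) {
    warn("degenerate pixel set: moments ellipse has zero minor axis",
         class = "coldpheno_degenerate_ellipse")
    minor <- 0
  }
  tibble(ellipse_center_x_px = mu[1], ellipse_center_y_px = mu[2],
         ellipse_major_px = major, ellipse_minor_px = minor,
         ellipse_angle_deg = if (major > 0) angle else 0,
         eccentricity = if (degenerate) NA_real_
                        else sqrt(1 - (minor / major)^2))
}

#' Percent necrotic tissue
#'
#' @param healthy_px,necrotic_px Pixel counts (vectorized).
#' @return `100 * necrotic / (healthy + necrotic)`.
#' @export
percent_necrosis <- function(healthy_px, necrotic_px) {
  total <- healthy_px + necrotic_px
  if (any(total <= 0)) {
    abort("plant has no pixels", class = "coldpheno_empty_plant")
  }
  100 * necrotic_px / total
}

# --- perimeter: Moore-neighbour boundary trace with sqrt(2) diagonals ---

# 8-neighbour offsets in clockwise order starting east (dx, dy)
MOORE <- cbind(dx = c(1, 1, 0, -1, -1, -1, 0, 1),
               dy = c(0, 1, 1, 1, 0, -1, -1, -1))

trace_perimeter <- function(mask) {
  xy <- which(mask, arr.ind = TRUE)     # row = y, col = x
  if (nrow(xy) == 1) return(1)
  inside <- function(y, x) {
    y >= 1 && y <= nrow(mask) && x >= 1 && x <= ncol(mask) && mask[y, x]
  }
  # start at the top-left-most pixel, entering from the west
  start <- xy[order(xy[, 1], xy[, 2])[1], ]
  sy <- start[1]; sx <- start[2]
  step_len <- c(1, sqrt(2))[1 + (MOORE[, "dx"] != 0 & MOORE[, "dy"] != 0)]
  total <- 0
  cy <- sy; cx <- sx
  dir <- 7L                            # entered from the west
  first_dir <- NA_integer_
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- (dir + k) %% 8 + 1L
      ny <- cy + MOORE[d, "dy"]; nx <- cx + MOORE[d, "dx"]
      if (inside(ny, nx)) {
        # stop when the trace is about to repeat its first move
        if (!is.na(first_dir) && cy == sy && cx == sx && d == first_dir) {
          return(total)
        }
        if (is.na(first_dir)) first_dir <- d
        total <- total + step_len[d]
        cy <- ny; cx <- nx
        dir <- (d - 1 + 5) %% 8        # backtrack direction + 1
        found <- TRUE
        break
      }
    }
    if (!found) return(max(total, 1))  # isolated pixel cluster
    if (total > 8 * nrow(xy)) return(total)  # safety stop
  }
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)      # 4-connected labels
  n <- max(lab)
  if (n <= 1) return(mask)
  # merge labels that touch diagonally to get 8-connected components
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  H <- nrow(lab); W <- ncol(lab)
  for (sh in list(c(1, 1), c(1, -1))) {
    a <- lab[1:(H - 1), if (sh[2] == 1) 1:(W - 1) else 2:W]
    b <- lab[2:H, if (sh[2] == 1) 2:W else 1:(W - 1)]
    touch <- unique(cbind(a[a > 0 & b > 0], b[a > 0 & b > 0]))
    for (r in seq_len(nrow(touch))) {
      ra <- find(touch[r, 1]); rb <- find(touch[r, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  merged <- matrix(0L, H, W)
  merged[lab > 0] <- root[lab[lab > 0]]
  counts <- tabulate(merged[merged > 0], nbins = n)
  merged == which.max(counts)
}

#' Extract the morphological trait vector of one plant
#'
#' Computes the sixteen morphological traits plus healthy/necrotic pixel
#' counts and percent necrosis from per-class binary masks. Height and
#' width use inclusive pixel extents (a single pixel has height and
#' width 1); area counts every plant pixel of either class; the
#' perimeter is the traced outer boundary length of the largest
#' connected component (diagonal steps count sqrt(2)); hull and ellipse
#' metrics are documented at [convex_hull_metrics()] and
#' [ellipse_moments()]. An empty mask yields a record with all-missing
#' traits and a `coldpheno_empty_plant` warning — never a dropped row.
#'
#' @param healthy,necrotic Binary matrices of equal dimensions (a
#'   necrotic mask of `NULL` is treated as empty).
#' @return A one-row tibble with the 16 traits, `healthy_px`,
#'   `necrotic_px`, `percent_necrosis` and an `empty` flag.
#' @export
extract_traits <- function(healthy, necrotic = NULL) {
  healthy <- as_binary_mask(healthy, "healthy")
  if (is.null(necrotic)) {
    necrotic <- matrix(FALSE, nrow(healthy), ncol(healthy))
  }
  necrotic <- as_binary_mask(necrotic, "necrotic")
  stopifnot(all(dim(healthy) == dim(necrotic)))
  plant <- healthy | necrotic
  n_healthy <- sum(healthy & !necrotic)
  n_necrotic <- sum(necrotic)

  if (!any(plant)) {
    warn("empty plant mask: emitting all-missing trait record",
         class = "coldpheno_empty_plant")
    out <- as_tibble(setNames(as.list(rep(NA_real_,
                                          length(morph_trait_names()))),
                              morph_trait_names()))
    out$healthy_px <- 0L; out$necrotic_px <- 0L
    out$percent_necrosis <- NA_real_; out$empty <- TRUE
    return(out)
  }

  xy <- mask_xy(plant)
  hull <- convex_hull_metrics(xy)
  ell <- withCallingHandlers(
    ellipse_moments(xy),
    coldpheno_degenerate_ellipse = function(w) invokeRestart("muffleWarning"))
  area <- nrow(xy)

  out <- tibble(
    height_px = diff(range(xy[, "y"])) + 1,
    width_px = diff(range(xy[, "x"])) + 1,
    area_px = area,
    perimeter_px = trace_perimeter(largest_component(plant))
  )
  out <- dplyr::bind_cols(out, hull)
  out$solidity <- area / out$hull_area_px
  out <- dplyr::bind_cols(out, ell)
  out$center_of_mass_x_px <- mean(xy[, "x"])
  out$center_of_mass_y_px <- mean(xy[, "y"])
  out <- out[morph_trait_names()]
  out$healthy_px <- n_healthy
  out$necrotic_px <- n_necrotic
  out$percent_necrosis <- percent_necrosis(n_healthy, n_necrotic)
  out$empty <- FALSE
  out
}
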