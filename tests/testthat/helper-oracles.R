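# independent brute-force oracles used across the suite

# shift a logical matrix by (dy, dx), zero-filled
shift_mask <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys - dy, xs - dx] <- m[ys, xs]
  out
}

# dilation by shift union + flood fill of border-connected background
oracle_dilate_fill <- function(m, radius = 1) {
  dil <- m
  for (dy in -radius:radius) for (dx in -radius:radius) {
    dil <- dil | shift_mask(m, dy, dx)
  }
  H <- nrow(m); W <- ncol(m)
  reach <- !dil & (row(m) == 1 | row(m) == H | col(m) == 1 | col(m) == W)
  repeat {
    grow <- reach
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      grow <- grow | (shift_mask(reach, sh[1], sh[2]) & !dil)
    }
    if (identical(grow, reach)) break
    reach <- grow
  }
  dil | (!dil & !reach)
}

# O(n^3) convex hull via brute-force edge validity; returns hull metrics
# on pixel centers with lattice-point hull area (degenerate: pixel count)
oracle_hull <- function(xy) {
  xy <- unique(xy[, 1:2, drop = FALSE])
  n <- nrow(xy)
  dmax <- if (n > 1) max(dist(xy)) else 0
  if (n == 1) return(list(area = 1, vertices = 1L, longest = 0))
  # collinearity: all cross products zero wrt first two distinct points
  v0 <- xy[2, ] - xy[1, ]
  cr <- (xy[, 1] - xy[1, 1]) * v0[2] - (xy[, 2] - xy[1, 2]) * v0[1]
  if (all(abs(cr) < 1e-9)) return(list(area = n, vertices = 2L, longest = dmax))
  edges <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    e <- xy[j, ] - xy[i, ]
    cr <- e[1] * (xy[, 2] - xy[i, 2]) - e[2] * (xy[, 1] - xy[i, 1])
    if (all(cr >= -1e-9)) edges[[length(edges) + 1]] <- c(i, j)
  }
  edges <- do.call(rbind, edges)
  # distinct edge directions = polygon sides = strict vertex count
  dirs <- t(apply(edges, 1, function(e) {
    d <- xy[e[2], ] - xy[e[1], ]
    d / sqrt(sum(d^2))
  }))
  nv <- nrow(unique(round(dirs, 9)))
  # lattice points inside all supporting half-planes
  gx <- seq(min(xy[, 1]), max(xy[, 1]))
  gy <- seq(min(xy[, 2]), max(xy[, 2]))
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  inside <- rep(TRUE, nrow(grid))
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    e <- xy[j, ] - xy[i, ]
    cr <- e[1] * (grid[, 2] - xy[i, 2]) - e[2] * (grid[, 1] - xy[i, 1])
    inside <- inside & cr >= -1e-9
  }
  list(area = sum(inside), vertices = nv, longest = dmax)
}

# direct kernel-sum density oracle at selected bins
oracle_kernel_density <- function(values, bandwidth, bins) {
  raw <- vapply(0:255, function(b) {
    sum(dnorm(b, mean = values, sd = bandwidth)) / length(values)
  }, numeric(1))
  raw <- raw + 1e-9
  (raw / sum(raw))[bins + 1]
}

# closed-form OLS slope
oracle_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# naive O(n^3) agglomerative clustering; returns merge heights
oracle_linkage_heights <- function(d, method = "complete") {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  link <- function(a, b) {
    vals <- d[a, b]
    if (method == "complete") max(vals) else min(vals)
  }
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i >= j) next
      h <- link(active[[i]], active[[j]])
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    heights <- c(heights, bh)
    active[[best[1]]] <- c(active[[best[1]]], active[[best[2]]])
    active[[best[2]]] <- NULL
  }
  heights
}

# small default-parameter design used across tests
tiny_design <- function(n_genotypes = 2, seed = 11, ...) {
  experiment_design(genotype_panel(n_genotypes, seed = seed),
                    replicates = 1, plots_per_treatment = 1,
                    seed = seed, ...)
}

# ground-truth class name per pixel, rack folded into background
truth_classes <- function(labels) {
  c("background", "background", "healthy", "necrotic")[labels + 1]
}
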