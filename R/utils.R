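# shared internal helpers

# deterministic child seed for image/plant i; stays well below 2^31
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483563) * 40014 + k * 40692) %% 2147483563L
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is_count(x, min)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "coldpheno_invalid_parameter")
  }
  invisible(as.integer(x))
}

# accept logical or 0/1 numeric matrices
as_binary_mask <- function(mask, name = "mask") {
  if (!is.matrix(mask)) abort(sprintf("`%s` must be a matrix", name))
  if (is.logical(mask)) return(mask)
  if (!all(mask %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary (logical or 0/1)", name))
  }
  mask > 0
}

assert_rgb_image <- function(image, name = "image") {
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L)) {
    abort(sprintf("`%s` must be an H x W x 3 RGB array", name))
  }
  invisible(image)
}

# mask coordinates as (x = column, y = row), 1-based
mask_xy <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}
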