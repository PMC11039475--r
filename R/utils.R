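# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a reproducible sub-seed for a pipeline stage from a base seed.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7 + offset) %% 2147483587L)
}

dims3 <- function(a) {
  d <- dim(a)
  stopifnot(length(d) == 3L)
  as.integer(d)
}

# Squared Euclidean distance (voxels) from every voxel to the nearest TRUE
# voxel of `mask`; returns array of same shape.
edt_sq <- function(mask) {
  d <- dims3(mask)
  array(cpp_edt_sq(as.logical(mask), d), dim = d)
}

# Euclidean distance transform in voxel units.
edt <- function(mask) sqrt(edt_sq(mask))

gaussian_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D numeric array (zero padded).
smooth_gauss3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dims3(a)
  array(cpp_sep_conv3(as.double(a), d, gaussian_kernel1d(sigma)), dim = d)
}

# Linear index <-> (x,y,z) subscripts, 1-based.
ind_to_xyz <- function(ind, d) {
  ind0 <- ind - 1L
  k <- ind0 %/% (d[1] * d[2])
  r <- ind0 %% (d[1] * d[2])
  cbind(x = r %% d[1] + 1L, y = r %/% d[1] + 1L, z = k + 1L)
}

xyz_to_ind <- function(xyz, d) {
  (xyz[, 1] - 1L) + d[1] * ((xyz[, 2] - 1L) + d[2] * (xyz[, 3] - 1L)) + 1L
}

# Bounding box of TRUE voxels, optionally padded and clipped to the grid.
bbox_of <- function(mask, pad = 0L) {
  d <- dims3(mask)
  w <- which(mask)
  if (length(w) == 0L) return(NULL)
  s <- ind_to_xyz(w, d)
  lo <- pmax(apply(s, 2, min) - pad, 1L)
  hi <- pmin(apply(s, 2, max) + pad, d)
  list(lo = lo, hi = hi)
}

crop_bbox <- function(a, bb) {
  a[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
}

# 26-connectivity binary dilation by one voxel.
dilate1 <- function(mask) {
  edt_sq(mask) <= 3
}

label_array <- function(mask, connectivity = 26L) {
  d <- dims3(mask)
  array(cpp_label_components(as.logical(mask), d, as.integer(connectivity)),
        dim = d)
}
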