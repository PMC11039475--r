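# Independent brute-force oracles and small geometric fixture builders.

# O(n^2) squared Euclidean distance to the nearest TRUE voxel
brute_edt_sq <- function(mask) {
  d <- dim(mask)
  pts <- which(mask, arr.ind = TRUE)
  out <- array(NA_real_, d)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3]))
        out[i, j, k] <- min(colSums((t(pts) - c(i, j, k))^2))
  out
}

# brute-force flood fill labelling under 6/18/26 connectivity
brute_label <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  m <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[m == 1, ], "18" = offs[m <= 2, ], offs)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    if (lab[idx[r, , drop = FALSE]] > 0L) next
    nxt <- nxt + 1L
    queue <- list(idx[r, ])
    lab[idx[r, , drop = FALSE]] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > d)) next
        qm <- matrix(q, 1)
        if (mask[qm] && lab[qm] == 0L) {
          lab[qm] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# is there a 26-connected path inside `allowed` linking a voxel adjacent
# to `from` with a voxel adjacent to `to`?
brute_path_exists <- function(allowed, from, to) {
  start <- allowed & infarct3d:::dilate1(from)
  goal <- allowed & infarct3d:::dilate1(to)
  if (!any(start) || !any(goal)) return(FALSE)
  lab <- infarct3d:::label_array(allowed, 26L)
  any(lab[start] %in% lab[goal] & lab[start] > 0L)
}

make_sphere <- function(r, n = 2 * r + 9, centre = NULL) {
  centre <- centre %||% rep((n + 1) / 2, 3)
  x <- 1:n
  dist <- sqrt(outer(outer((x - centre[1])^2, (x - centre[2])^2, "+"),
                     (x - centre[3])^2, "+"))
  array(dist <= r, dim = c(n, n, n))
}

make_cube <- function(a, n = a + 10) {
  m <- array(FALSE, dim = c(n, n, n))
  s <- 6:(5 + a)
  m[s, s, s] <- TRUE
  m
}

make_two_spheres <- function(r = 10, sep = 1.5) {
  nx <- round(4 * r + sep * r)
  ny <- round(2 * r + 8)
  m <- array(FALSE, dim = c(nx, ny, ny))
  c1 <- c((nx - sep * r) / 2, ny / 2, ny / 2)
  c2 <- c1 + c(sep * r, 0, 0)
  x <- 1:nx; y <- 1:ny
  d1 <- sqrt(outer(outer((x - c1[1])^2, (y - c1[2])^2, "+"),
                   (y - c1[3])^2, "+"))
  d2 <- sqrt(outer(outer((x - c2[1])^2, (y - c2[2])^2, "+"),
                   (y - c2[3])^2, "+"))
  m[d1 <= r | d2 <= r] <- TRUE
  m
}

# rasterized cylinder through a cube, random orientation
make_cylinder <- function(radius_vox, n = 48, dir = NULL, half = 15) {
  dir <- dir %||% {
    v <- stats::rnorm(3); v / sqrt(sum(v^2))
  }
  c0 <- rep(n / 2, 3)
  p <- c0 - dir * half; q <- c0 + dir * half
  xs <- 1:n
  gx <- rep(xs, n * n); gy <- rep(rep(xs, each = n), n)
  gz <- rep(xs, each = n * n)
  v <- q - p; vv <- sum(v^2)
  t <- pmin(pmax(((gx - p[1]) * v[1] + (gy - p[2]) * v[2] +
                    (gz - p[3]) * v[3]) / vv, 0), 1)
  dx <- gx - p[1] - t * v[1]; dy <- gy - p[2] - t * v[2]
  dz <- gz - p[3] - t * v[3]
  array(dx * dx + dy * dy + dz * dz <= radius_vox^2, dim = c(n, n, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
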