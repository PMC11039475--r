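# Synthetic vascular trees.
#
# The portal and central/hepatic vein trees are generated as random
# recursive bifurcations entering from opposite grid faces, interdigitated
# by offsetting their root grids by half a spacing. Branch length and
# radius decay geometrically with depth. The tree topology is invented
# plumbing: it is chosen for plausibility and spatial coverage (so every
# parenchyma voxel has a finite, moderate distance to both trees), not
# taken from measured vascular geometry.

# rotate unit vector v by angle `ang` around unit axis `ax` (Rodrigues)
rotate_about <- function(v, ax, ang) {
  v * cos(ang) + cross3(ax, v) * sin(ang) +
    ax * sum(ax * v) * (1 - cos(ang))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

random_perpendicular <- function(v) {
  repeat {
    u <- stats::rnorm(3)
    u <- u - sum(u * v) * v
    n <- sqrt(sum(u^2))
    if (n > 1e-6) return(u / n)
  }
}

# Recursively grow one tree; returns a matrix of segments
# (x0,y0,z0,x1,y1,z1,radius). `obstacle_dist`, if given, is a distance
# field to a previously grown tree: proposed segments are truncated
# before they come within `radius + 1.5` voxels of it, so the two trees
# interdigitate without ever touching (no branch is ever cut after the
# fact, which would disconnect a subtree).
grow_tree <- function(root, dir, len, radius, depth, d, margin = 2,
                      obstacle_dist = NULL) {
  acc <- list()
  free_prefix <- function(p, q, radius) {
    if (is.null(obstacle_dist)) return(q)
    L <- sqrt(sum((q - p)^2))
    if (L < 1) return(q)
    ts <- seq(0, 1, by = 1 / ceiling(L))
    for (t in ts) {
      s <- p + t * (q - p)
      if (obstacle_dist[matrix(pmin(pmax(round(s), 1), d), 1)] <=
          radius + 1.5)
        return(if (t <= 2 / L) NULL else p + max(t - 1.5 / L, 0) * (q - p))
    }
    q
  }
  grow <- function(p, dir, len, radius, depth) {
    # on collision with the obstacle tree, retry with a deflected
    # direction a few times and keep the longest feasible run
    best_q <- NULL; best_len <- -1
    for (attempt in seq_len(6L)) {
      dd <- if (attempt == 1L) dir else {
        a2 <- rotate_about(dir, random_perpendicular(dir),
                           stats::runif(1, 0.3, 0.9))
        a2 / sqrt(sum(a2^2))
      }
      q <- pmin(pmax(p + dd * len, margin), d - margin)
      q <- free_prefix(p, q, radius)
      if (!is.null(q)) {
        run <- sqrt(sum((q - p)^2))
        if (run > best_len) { best_len <- run; best_q <- q }
        if (run >= 0.6 * len) break
      }
    }
    if (is.null(best_q)) return(invisible())
    q <- best_q
    acc[[length(acc) + 1L]] <<- c(p, q, radius)
    if (depth <= 0L) return(invisible())
    dir_eff <- (q - p) / max(sqrt(sum((q - p)^2)), 1e-9)
    ax <- random_perpendicular(dir_eff)
    for (sgn in c(1, -1)) {
      ang <- sgn * stats::rnorm(1, 35, 8) * pi / 180
      nd <- rotate_about(dir_eff, ax, ang)
      # small azimuthal jitter out of the branching plane
      nd <- rotate_about(nd, dir_eff, stats::runif(1, -0.6, 0.6))
      nd <- nd / sqrt(sum(nd^2))
      grow(q, nd, len * stats::runif(1, 0.65, 0.8),
           max(radius * 0.75, 1), depth - 1L)
    }
  }
  grow(root, dir, len, radius, depth)
  if (length(acc) == 0L) return(NULL)
  do.call(rbind, acc)
}

# Rasterize tube segments into a logical mask; voxels already TRUE in
# `avoid` are skipped (keeps trees disjoint by construction).
rasterize_segments <- function(d, segs, avoid = NULL) {
  mask <- array(FALSE, dim = d)
  for (s in seq_len(nrow(segs))) {
    p <- segs[s, 1:3]; q <- segs[s, 4:6]; r <- segs[s, 7]
    lo <- pmax(floor(pmin(p, q) - r - 1), 1)
    hi <- pmin(ceiling(pmax(p, q) + r + 1), d)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    v <- q - p
    vv <- sum(v^2)
    # distance from every voxel centre in the box to the segment
    gx <- rep(xs, times = length(ys) * length(zs))
    gy <- rep(rep(ys, each = length(xs)), times = length(zs))
    gz <- rep(zs, each = length(xs) * length(ys))
    wx <- gx - p[1]; wy <- gy - p[2]; wz <- gz - p[3]
    t <- if (vv > 0) pmin(pmax((wx * v[1] + wy * v[2] + wz * v[3]) / vv, 0), 1)
         else 0
    dx <- wx - t * v[1]; dy <- wy - t * v[2]; dz <- wz - t * v[3]
    inside <- dx * dx + dy * dy + dz * dz <= r * r
    if (any(inside)) {
      sub <- cbind(gx[inside], gy[inside], gz[inside])
      mask[sub] <- TRUE
    }
  }
  if (!is.null(avoid)) mask <- mask & !avoid
  mask
}

#' Generate the synthetic vascular trees
#'
#' Builds the portal and central/hepatic vein trees (plus, at the
#' submicron scale, a sinusoid network of randomly oriented thin tubes)
#' and returns them as a `phantom_truth` label grid. Portal and central
#' labels are disjoint by construction.
#'
#' @param params a [phantom_params()] object.
#' @param sinusoid_diameter_um sinusoid tube diameter (submicron scale
#'   only).
#' @return A `phantom_truth` object: integer `labels` array (0 =
#'   parenchyma, 1 = portal, 2 = central, 3 = sinusoid), empty infarct
#'   and channel tables, and generation metadata.
#' @export
build_vessel_trees <- function(params, sinusoid_diameter_um = 6.5) {
  d <- params$grid_shape
  if (min(d) < 24)
    stop("grid too small to place non-overlapping portal tree ",
         "(need at least 24 voxels per axis)")
  if (params$scale == "submicron")
    return(build_lobule_vessels(params, sinusoid_diameter_um))
  with_seed(stage_seed(params$seed, 101L), {
    depth <- if (min(d) >= 192) 6L else if (min(d) >= 96) 5L else 4L
    spacing <- 36
    nro_y <- max(1L, floor(d[2] / spacing))
    nro_z <- max(1L, floor(d[3] / spacing))
    radius0 <- min(6, max(2.5, 0.03 * min(d)))
    len0 <- 0.28 * d[1]

    make_tree <- function(face, obstacle_dist = NULL) {
      segs <- list()
      for (iy in seq_len(nro_y))
        for (iz in seq_len(nro_z)) {
          y0 <- (iy - 0.5) * d[2] / nro_y + stats::runif(1, -4, 4)
          z0 <- (iz - 0.5) * d[3] / nro_z + stats::runif(1, -4, 4)
          if (face == "low") {
            root <- c(1, y0, z0); dir <- c(1, 0, 0)
          } else {
            # offset half a spacing for interdigitation
            y0 <- (y0 + d[2] / (2 * nro_y)) %% d[2]
            z0 <- (z0 + d[3] / (2 * nro_z)) %% d[3]
            root <- c(d[1], y0, z0); dir <- c(-1, 0, 0)
          }
          dir <- dir + c(0, stats::runif(1, -0.15, 0.15),
                         stats::runif(1, -0.15, 0.15))
          dir <- dir / sqrt(sum(dir^2))
          segs[[length(segs) + 1L]] <-
            grow_tree(root, dir, len0, radius0, depth, d,
                      obstacle_dist = obstacle_dist)
        }
      do.call(rbind, segs)
    }

    portal <- rasterize_segments(d, make_tree("low"))
    # the central tree is grown with the portal tree as an obstacle, so
    # the trees interdigitate without touching; the extra one-voxel
    # avoidance belt guarantees they are never 26-adjacent
    central <- rasterize_segments(d, make_tree("high", edt(portal)),
                                  avoid = dilate1(portal))
    if (!any(portal)) stop("grid too small to place portal tree")
    if (!any(central))
      stop("grid too small to place non-overlapping central tree")

    labels <- array(0L, dim = d)
    labels[portal] <- LBL_PORTAL
    labels[central] <- LBL_CENTRAL
    new_phantom_truth(labels, params)
  })
}

new_phantom_truth <- function(labels, params) {
  empty_inf <- data.frame(infarct_id = integer(0), cluster_id = integer(0),
                          origin_zone = integer(0), n_blobs = integer(0),
                          volume_um3 = numeric(0), n_channels = integer(0),
                          channel_diam_um = numeric(0),
                          cx = numeric(0), cy = numeric(0), cz = numeric(0),
                          r_vox = numeric(0))
  empty_ch <- data.frame(channel_id = integer(0), infarct_id = integer(0),
                         diameter_um = numeric(0), n_voxels = integer(0))
  structure(list(labels = labels, voxel_size_um = params$voxel_size_um,
                 scale = params$scale, day = params$day,
                 seed = params$seed, infarct_table = empty_inf,
                 channel_table = empty_ch),
            class = "phantom_truth")
}

# Submicron-scale vasculature: one lobule volume of interest holding a
# single central-vein trunk through the middle, two portal trunks at
# opposite edges (short side branches each), and a network of randomly
# oriented sinusoid tubes filling the parenchyma. Vein radii are
# physical: the central vein is an order of magnitude wider than a
# sinusoid or a microchannel, which is what lets the analysis separate
# vein trunks from candidate channel lumina by interior radius.
build_lobule_vessels <- function(params, sinusoid_diameter_um = 6.5,
                                 central_radius_um = NULL,
                                 portal_radius_um = NULL) {
  d <- params$grid_shape
  vs <- params$voxel_size_um
  # vein calibre shrinks with the volume of interest so small test grids
  # remain placeable; at the reference 128^3 VOI the central vein is 9 um
  central_radius_um <- central_radius_um %||% min(9, 0.11 * min(d) * vs)
  portal_radius_um <- portal_radius_um %||% min(6.5, 0.08 * min(d) * vs)
  with_seed(stage_seed(params$seed, 101L), {
    rc <- central_radius_um / vs
    rp <- portal_radius_um / vs
    jit <- function(k) stats::runif(k, -0.05 * min(d), 0.05 * min(d))
    cx <- d[1] / 2; cy <- d[2] / 2
    segs_c <- list(c(cx + jit(1), cy + jit(1), 2,
                     cx + jit(1), cy + jit(1), d[3] - 1, rc))
    for (b in 1:3) {
      z0 <- stats::runif(1, 0.25, 0.75) * d[3]
      dir <- c(stats::rnorm(2), stats::runif(1, -0.3, 0.3))
      dir <- dir / sqrt(sum(dir^2))
      p <- c(cx, cy, z0)
      segs_c[[length(segs_c) + 1L]] <- c(p, p + dir * 0.35 * min(d),
                                         0.5 * rc)
    }
    central <- rasterize_segments(d, do.call(rbind, segs_c))

    segs_p <- list()
    for (corner in list(c(0.12, 0.12), c(0.88, 0.88))) {
      px <- corner[1] * d[1]; py <- corner[2] * d[2]
      segs_p[[length(segs_p) + 1L]] <-
        c(px + jit(1), py + jit(1), 2,
          px + jit(1), py + jit(1), d[3] - 1, rp)
      for (b in 1:2) {
        z0 <- stats::runif(1, 0.2, 0.8) * d[3]
        dir <- c(stats::rnorm(2), stats::runif(1, -0.3, 0.3))
        dir <- dir / sqrt(sum(dir^2))
        p <- c(px, py, z0)
        segs_p[[length(segs_p) + 1L]] <- c(p, p + dir * 0.25 * min(d),
                                           0.5 * rp)
      }
    }
    portal <- rasterize_segments(d, do.call(rbind, segs_p),
                                 avoid = dilate1(central))
    if (!any(portal)) stop("grid too small to place portal tree")
    if (!any(central)) stop("grid too small to place central tree")

    # sinusoids pervade the whole VOI (long chords through the volume),
    # so every lesion, including border-clipped ones, has one nearby
    rs <- sinusoid_diameter_um / vs / 2
    n_sin <- max(10L, round(prod(d) / 8e4))
    segs <- matrix(0, nrow = n_sin, ncol = 7)
    for (s in seq_len(n_sin)) {
      ctr <- stats::runif(3, 0.02, 0.98) * d
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      half <- 0.75 * min(d)
      segs[s, ] <- c(ctr - dir * half, ctr + dir * half, rs)
    }
    sinus <- rasterize_segments(d, segs,
                                avoid = dilate1(portal | central))

    labels <- array(0L, dim = d)
    labels[portal] <- LBL_PORTAL
    labels[central] <- LBL_CENTRAL
    labels[sinus] <- LBL_SINUSOID
    new_phantom_truth(labels, params)
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<phantom_truth> day %s, %s scale, %dx%dx%d, seed %d\n",
              x$day, x$scale, d[1], d[2], d[3], x$seed))
  cat(sprintf("  %d infarct units, %d microchannels\n",
              nrow(x$infarct_table), nrow(x$channel_table)))
  invisible(x)
}
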