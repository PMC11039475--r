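# Infarct placement.
#
# Each infarct unit is a perturbed sphere (or, with probability
# confluent_fraction, a fused cluster of 2-3 overlapping perturbed
# spheres sharing one cluster ID). Unit centres are sampled from the
# parenchyma of the acinus zone drawn from zone_placement_weights, so the
# day presets reproduce the zone-I-to-zone-III migration of the lesions.
# Surface roughness is a smooth random radial perturbation whose
# amplitude grows with the day preset, mimicking the progressive loss of
# sphericity.

# Smooth unit-variance random field over a box, by trilinear upsampling of
# a coarse N(0,1) grid.
coarse_noise_field <- function(db, nc = 4L) {
  g <- array(stats::rnorm(nc^3), dim = c(nc, nc, nc))
  for (ax in 1:3) {
    u <- seq(1, nc, length.out = db[ax])
    g <- apply(g, c(2, 3), function(v)
      stats::approx(seq_along(v), v, u)$y)
    g <- aperm(g, c(2, 3, 1))  # interpolated axis to the back
  }
  # after three cycles the axes are back in order
  g
}

# Voxel linear indices of one perturbed-sphere blob.
blob_voxels <- function(d, centre, r_vox, roughness) {
  rmax <- r_vox * (1 + 2.2 * roughness) + 1
  lo <- pmax(floor(centre - rmax), 1)
  hi <- pmin(ceiling(centre + rmax), d)
  db <- hi - lo + 1L
  if (any(db < 1L)) return(integer(0))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- (xs - centre[1])^2
  dy2 <- (ys - centre[2])^2
  dz2 <- (zs - centre[3])^2
  dist <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  if (roughness > 0) {
    g <- pmin(pmax(coarse_noise_field(db), -2), 2)
    rloc <- r_vox * (1 + roughness * g)
  } else rloc <- r_vox
  inside <- dist <= rloc
  which(inside) |> local_to_global(lo, db, d)
}

local_to_global <- function(ind, lo, db, d) {
  s <- ind_to_xyz(ind, db)
  xyz_to_ind(cbind(s[, 1] + lo[1] - 1L, s[, 2] + lo[2] - 1L,
                   s[, 3] + lo[3] - 1L), d)
}

#' Place infarct units into a phantom
#'
#' Adds `params$n_infarcts` infarct units to the truth grid. A unit is a
#' single perturbed sphere or, with probability
#' `params$confluent_fraction`, a fused cluster of 2-3 overlapping
#' spheres recorded under one cluster ID. Unit centres are drawn from the
#' acinus zone sampled from `zone_placement_weights`; no infarct voxel
#' overlaps vessel or sinusoid lumina, units never touch each other, and
#' placement aborts with a capacity error when the requested count cannot
#' be placed within the occupancy cap (40% of parenchyma by default).
#'
#' @param params a [phantom_params()] object.
#' @param truth `phantom_truth` from [build_vessel_trees()].
#' @param zones `zone_map` computed from the same vessel grid.
#' @param occupancy_cap maximum infarct volume as a fraction of
#'   parenchyma.
#' @return The updated `phantom_truth` with labelled infarcts and a
#'   filled `infarct_table`.
#' @export
place_infarcts <- function(params, truth, zones, occupancy_cap = 0.4) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(zones, "zone_map"))
  d <- dims3(truth$labels)
  if (!identical(d, dims3(zones$zones)))
    stop("zones must be computed from the same grid")
  n <- params$n_infarcts
  if (n == 0L) return(truth)
  labels <- truth$labels
  vs <- params$voxel_size_um
  parenchyma_n <- sum(labels == 0L)
  cap_vox <- occupancy_cap * parenchyma_n
  vessel_dist <- edt(labels == LBL_PORTAL | labels == LBL_CENTRAL)
  zidx <- lapply(1:3, function(z) which(labels == 0L & zones$zones == z))
  rr_vox <- params$infarct_radius_um_range / vs
  rough <- params$sphericity_roughness

  with_seed(stage_seed(params$seed, 202L), {
    centres <- matrix(numeric(0), ncol = 3)
    eff_radii <- numeric(0)
    rows <- list()
    placed_vox <- 0
    for (u in seq_len(n)) {
      r_vox <- stats::runif(1, rr_vox[1], rr_vox[2])
      is_cl <- stats::runif(1) < params$confluent_fraction
      zone_u <- sample.int(3L, 1L, prob = params$zone_placement_weights)
      # loose spacing heuristic; the hard no-touch guarantee is the
      # adjacency check below, which triggers a retry
      r_eff <- r_vox * 1.25
      # a whole-lobe phantom keeps lesions clear of the grid border (the
      # border is an artificial crop); a submicron volume of interest is
      # itself a crop of tissue, so lesions may be clipped by it -- and
      # zone I, the shell farthest from the single central vein, lies
      # along the VOI border, so day-1 placement depends on it
      margin <- if (params$scale == "submicron") 3 else r_eff + 2
      ok <- FALSE
      for (try in seq_len(1500L)) {
        cand <- zidx[[zone_u]]
        if (length(cand) == 0L) break
        c0 <- as.numeric(ind_to_xyz(cand[sample.int(length(cand), 1L)], d))
        if (vessel_dist[matrix(round(c0), 1)] <= 2) next
        if (any(c0 < margin) || any(c0 > d - margin + 1)) next
        if (nrow(centres) > 0) {
          dd <- sqrt(rowSums((centres - matrix(c0, nrow(centres), 3,
                                               byrow = TRUE))^2))
          if (any(dd < eff_radii + r_eff + 2)) next
        }
        vox <- blob_voxels(d, c0, r_vox, rough)
        n_blobs <- 1L
        if (is_cl) {
          n_sat <- sample.int(2L, 1L)
          n_blobs <- 1L + n_sat
          for (s in seq_len(n_sat)) {
            dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
            rs <- r_vox * stats::runif(1, 0.75, 0.9)
            cs <- c0 + dir * 0.98 * (r_vox + rs)
            vox <- union(vox, blob_voxels(d, cs, rs, rough))
          }
        }
        # infarcts may not enter the vein lumina; at the submicron scale
        # they do invade and replace sinusoid space, as the lesions do in
        # cholestatic tissue
        vox <- vox[labels[vox] == 0L | labels[vox] == LBL_SINUSOID]
        if (length(vox) < 4L) next
        # unit must be one component and must not touch other infarcts
        bbm <- array(FALSE, dim = d); bbm[vox] <- TRUE
        bb <- bbox_of(bbm, pad = 1L)
        mc <- crop_bbox(bbm, bb)
        if (max(label_array(mc, 26L)) != 1L) next
        near <- crop_bbox(labels, bb)
        if (any(dilate1(mc) & near >= LBL_INFARCT0)) next
        if (placed_vox + length(vox) > cap_vox)
          stop("capacity: occupancy cap (", round(100 * occupancy_cap),
               "% of parenchyma) exceeded while placing infarct ", u)
        labels[vox] <- LBL_INFARCT0 + u
        placed_vox <- placed_vox + length(vox)
        centres <- rbind(centres, c0)
        eff_radii <- c(eff_radii, r_eff)
        rows[[u]] <- data.frame(
          infarct_id = u, cluster_id = u, origin_zone = zone_u,
          n_blobs = n_blobs, volume_um3 = length(vox) * vs^3,
          n_channels = 0L, channel_diam_um = NA_real_,
          cx = c0[1], cy = c0[2], cz = c0[3], r_vox = r_vox)
        ok <- TRUE
        break
      }
      if (!ok)
        stop("capacity: could not place infarct ", u, " of ", n,
             " without violating the occupancy/overlap constraints")
    }
    truth$labels <- labels
    truth$infarct_table <- do.call(rbind, rows)
    truth
  })
}
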