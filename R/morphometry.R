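#' Volume, surface area and sphericity of one component
#'
#' Volume is the voxel count scaled by the voxel volume. Surface area is
#' measured on a triangulated 0.5-isosurface (marching tetrahedra) of the
#' mask after mild Gaussian smoothing; naive voxel-face counting is not
#' used because it overestimates the area of smooth bodies by roughly 50%,
#' which would destroy the sphericity scale. Sphericity is
#' \deqn{\Psi = \pi^{1/3} (6V)^{2/3} / A,}
#' equal to 1 for a perfect sphere and smaller for irregular shapes.
#'
#' @param mask logical 3D array holding a single connected component.
#' @param voxel_size_um voxel edge length in micrometres.
#' @param smooth_sigma Gaussian pre-smoothing (voxels) applied before
#'   surface triangulation; 0 disables. The default is a compromise
#'   validated against analytic spheres and cubes; for components so small
#'   that smoothing erases the isosurface the function falls back to the
#'   raw binary surface.
#' @return list with `V_um3`, `A_um2`, `psi` and `border` (`TRUE` when the
#'   component touches the grid border, in which case the surface is
#'   truncated and `psi` should not be trusted).
#' @export
measure_component <- function(mask, voxel_size_um, smooth_sigma = 0.7) {
  d <- dims3(mask)
  nvox <- sum(mask)
  if (nvox == 0L) stop("empty component")
  V <- nvox * voxel_size_um^3
  bb <- bbox_of(mask)
  border <- any(bb$lo == 1L) || any(bb$hi == d)
  pad <- max(2L, ceiling(3 * smooth_sigma) + 1L)
  m <- crop_bbox(mask, bb)
  dm <- dim(m)
  field <- array(0, dim = dm + 2L * pad)
  field[pad + seq_len(dm[1]), pad + seq_len(dm[2]), pad + seq_len(dm[3])] <-
    as.double(m)
  if (smooth_sigma > 0) {
    sm <- smooth_gauss3(field, smooth_sigma)
    if (max(sm) > 0.5) field <- sm  # else: fall back to the binary surface
  }
  area_vox <- cpp_march_tet_area(as.double(field), dim(field), 0.5)
  A <- area_vox * voxel_size_um^2
  psi <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  list(V_um3 = V, A_um2 = A, psi = psi, border = border)
}

#' Measure every labelled infarct component
#'
#' @param labels integer 3D array of component labels (0 = background).
#' @param voxel_size_um voxel edge length in micrometres.
#' @param smooth_sigma passed to [measure_component()].
#' @return data.frame with one row per component: `id`, `n_voxels`,
#'   `V_um3`, `A_um2`, `psi`, `border`, and the physical centroid
#'   `cx_um`, `cy_um`, `cz_um`.
#' @export
measure_components <- function(labels, voxel_size_um, smooth_sigma = 0.7) {
  d <- dims3(labels)
  ids <- sort(unique(labels[labels > 0L]))
  out <- data.frame(id = integer(0), n_voxels = integer(0),
                    V_um3 = numeric(0), A_um2 = numeric(0),
                    psi = numeric(0), border = logical(0),
                    cx_um = numeric(0), cy_um = numeric(0),
                    cz_um = numeric(0))
  for (id in ids) {
    m <- labels == id
    mm <- measure_component(m, voxel_size_um, smooth_sigma)
    s <- ind_to_xyz(which(m), d)
    out <- rbind(out, data.frame(
      id = id, n_voxels = sum(m), V_um3 = mm$V_um3, A_um2 = mm$A_um2,
      psi = mm$psi, border = mm$border,
      cx_um = (mean(s[, 1]) - 1) * voxel_size_um,
      cy_um = (mean(s[, 2]) - 1) * voxel_size_um,
      cz_um = (mean(s[, 3]) - 1) * voxel_size_um))
  }
  out
}

#' Classify a component as an individual or confluent infarct
#'
#' Operationalises the visual distinction between an individually grown
#' infarct and one formed by fusion of several infarcts: the interior
#' distance transform of the component is searched for h-maxima cores
#' (suppressing maxima shallower than `h_voxels`), the component is split
#' into basins by a seeded watershed on the distance map, and it is called
#' confluent when at least two cores own a basin of at least
#' `min_core_fraction` of the component volume.
#'
#' @param mask logical 3D array, a single component.
#' @param voxel_size_um voxel edge length in micrometres (kept for
#'   interface symmetry; the rule operates in voxel units).
#' @param h_voxels depth threshold (voxels) for a distance maximum to
#'   count as a separate core.
#' @param min_core_fraction minimum basin volume, as a fraction of the
#'   component volume, for a core to count.
#' @return list with `confluence` (`"individual"` or `"confluent"`),
#'   `n_cores`, and the basin volume fractions.
#' @export
classify_confluence <- function(mask, voxel_size_um, h_voxels = 2,
                                min_core_fraction = 0.1) {
  nvox <- sum(mask)
  if (nvox == 0L) stop("empty component")
  bb <- bbox_of(mask, pad = 1L)
  m <- crop_bbox(mask, bb)
  dm <- dim(m)
  dt <- edt(!m)
  dt[!m] <- 0
  marker <- pmax(dt - h_voxels, 0)
  recon <- array(cpp_grey_reconstruct(as.double(marker), as.double(dt), dm),
                 dim = dm)
  cores <- array(cpp_regional_maxima(as.double(recon), as.logical(m), dm),
                 dim = dm)
  core_lab <- label_array(cores, 26L)
  ncand <- max(core_lab)
  if (ncand <= 1L)
    return(list(confluence = "individual", n_cores = max(1L, ncand),
                basin_fractions = 1))
  basins <- array(cpp_watershed(as.double(dt), as.integer(core_lab),
                                as.logical(m), dm), dim = dm)
  bv <- tabulate(basins[basins > 0L], nbins = ncand)
  fr <- bv / sum(m)
  n_cores <- sum(fr >= min_core_fraction)
  list(confluence = if (n_cores >= 2L) "confluent" else "individual",
       n_cores = max(1L, n_cores), basin_fractions = fr)
}

# Shortest (cost-weighted) path between voxel sets inside a mask; the cost
# 1/(0.5 + r) with r the interior radius keeps the path on the medial axis.
centreline_path <- function(mask, redt, from_idx, to_idx) {
  dm <- dims3(mask)
  cost <- 1 / (0.5 + as.double(redt))
  res <- cpp_dijkstra(as.logical(mask), dm, from_idx - 1L, cost)
  dd <- res$dist[to_idx]
  if (all(!is.finite(dd))) return(NULL)
  cur <- to_idx[which.min(dd)]
  path <- integer(0)
  while (cur != -1L + 1L && length(path) < prod(dm)) {
    path <- c(path, cur)
    prev <- res$pred[cur] + 1L
    if (prev == 0L) break
    cur <- prev
  }
  rev(path)
}

#' Estimate the diameter of a tubular structure
#'
#' Extracts a centreline between the two ends of the tube (the pair of
#' most geodesically distant voxels) and averages twice the interior
#' radius, measured by the Euclidean distance transform, along it. Path
#' voxels within one maximal radius of either end are trimmed so the open
#' end caps do not bias the estimate.
#'
#' @param mask logical 3D array containing one tube.
#' @param voxel_size_um voxel edge length in micrometres.
#' @param correction_vox optional discretisation offset (voxels)
#'   subtracted from the radius before doubling; the default 0 is
#'   calibrated on rasterized cylinders (see the methods vignette).
#' @return list with `diam_mean_um`, `diam_min_um`, `n_path`.
#' @export
measure_tube_diameter <- function(mask, voxel_size_um,
                                  correction_vox = 0) {
  bb <- bbox_of(mask, pad = 2L)
  m <- crop_bbox(mask, bb)
  dm <- dim(m)
  idx <- which(m)
  if (length(idx) < 3L) stop("tube too small to measure")
  redt <- edt(!m)
  # two-sweep farthest-pair search for the tube endpoints
  ones <- rep(1.0, prod(dm))
  r1 <- cpp_dijkstra(as.logical(m), dm, idx[1] - 1L, ones)
  e1 <- idx[which.max(replace(r1$dist[idx], !is.finite(r1$dist[idx]), -1))]
  r2 <- cpp_dijkstra(as.logical(m), dm, e1 - 1L, ones)
  e2 <- idx[which.max(replace(r2$dist[idx], !is.finite(r2$dist[idx]), -1))]
  path <- centreline_path(m, redt, e1, e2)
  if (is.null(path)) stop("tube endpoints are not connected")
  k <- ceiling(max(redt[path]))
  if (length(path) > 2 * k + 3) path <- path[(k + 1):(length(path) - k)]
  r <- pmax(redt[path] - correction_vox, 0.5)
  list(diam_mean_um = mean(2 * r) * voxel_size_um,
       diam_min_um = min(2 * r) * voxel_size_um,
       n_path = length(path))
}

#' Detect infarct-sinusoidal microchannels
#'
#' Searches, for every infarct, the dark lumen voxels in a shell around it
#' for tubular connections to the sinusoid network. A microchannel is a
#' centreline path through a lumen component whose endpoints touch the
#' infarct surface and a sinusoid; distinct contact patches on the infarct
#' surface give distinct channels, and channels sharing more than half
#' their voxels are merged. The channel diameter is twice the interior
#' radius (distance to the nearest tissue voxel, with the infarct and
#' sinusoid lumina treated as open so the end caps do not truncate it)
#' averaged along the centreline.
#'
#' @param infarcts integer 3D array of infarct labels (0 = background), or
#'   a logical mask for a single infarct.
#' @param sinusoids logical 3D array of sinusoid lumina.
#' @param lumen logical 3D array of sub-threshold (dark) voxels outside
#'   both structures.
#' @param voxel_size_um voxel edge length in micrometres.
#' @param shell_um search-shell thickness around each infarct.
#' @param min_channel_voxels smallest lumen component considered.
#' @param correction_vox see [measure_tube_diameter()].
#' @return list with per-channel data.frame `channels` and per-infarct
#'   data.frame `per_infarct` (`id`, `n_channels`, `mean_diam_um`).
#'   Channels whose diameter resolves to fewer than 2 voxels are flagged
#'   `reliable = FALSE`.
#' @export
detect_microchannels <- function(infarcts, sinusoids, lumen, voxel_size_um,
                                 shell_um = 13, min_channel_voxels = 4L,
                                 correction_vox = 0) {
  if (is.null(sinusoids)) stop("sinusoid mask is required")
  if (is.logical(infarcts)) infarcts <- array(as.integer(infarcts),
                                              dim = dim(infarcts))
  d <- dims3(infarcts)
  if (!identical(d, dims3(sinusoids)) || !identical(d, dims3(lumen)))
    stop("masks must share one grid")
  if (any(lumen & (sinusoids | infarcts > 0L)))
    stop("lumen mask must be disjoint from infarcts and sinusoids")
  shell_vox <- shell_um / voxel_size_um
  ids <- sort(unique(infarcts[infarcts > 0L]))
  chans <- data.frame(infarct_id = integer(0), channel = integer(0),
                      n_voxels = integer(0), diam_mean_um = numeric(0),
                      diam_min_um = numeric(0), reliable = logical(0))
  for (id in ids) {
    inf_full <- infarcts == id
    bb <- bbox_of(inf_full, pad = ceiling(shell_vox) + 2L)
    inf_c <- crop_bbox(inf_full, bb)
    sin_c <- crop_bbox(sinusoids, bb)
    lum_c <- crop_bbox(lumen, bb) & crop_bbox(infarcts == 0L, bb)
    dm <- dim(inf_c)
    shell <- edt(inf_c) <= shell_vox & !inf_c
    cand <- lum_c & shell & !sin_c
    if (!any(cand)) next
    open <- cand | inf_c | sin_c
    redt <- edt(!open)
    comp <- label_array(cand, 26L)
    touch_inf <- cand & dilate1(inf_c)
    touch_sin <- cand & dilate1(sin_c)
    paths <- list()
    for (cc in seq_len(max(comp))) {
      inmask <- comp == cc
      if (sum(inmask) < min_channel_voxels) next
      src_all <- which(inmask & touch_inf)
      tgt <- which(inmask & touch_sin)
      if (length(src_all) == 0L || length(tgt) == 0L) next
      patch_holder <- array(FALSE, dm); patch_holder[src_all] <- TRUE
      patches <- label_array(patch_holder, 26L)
      for (pp in seq_len(max(patches))) {
        src <- which(patches == pp)
        path <- centreline_path(inmask, redt, src, tgt)
        if (!is.null(path)) paths[[length(paths) + 1L]] <- path
      }
    }
    # merge paths sharing > 50% of their voxels
    keep <- rep(TRUE, length(paths))
    if (length(paths) > 1L)
      for (a in seq_along(paths))
        for (b in seq_len(a - 1L))
          if (keep[a] && keep[b]) {
            ov <- length(intersect(paths[[a]], paths[[b]])) /
              min(length(paths[[a]]), length(paths[[b]]))
            if (ov > 0.5) keep[a] <- FALSE
          }
    paths <- paths[keep]
    for (ch in seq_along(paths)) {
      # diameter from the medial core of the lumen the path runs through:
      # the path itself connects surface contact patches and so hugs the
      # wall near its ends, biasing a direct path average low
      pvox <- paths[[ch]]
      cc <- comp[pvox[ceiling(length(pvox) / 2)]]
      pm <- array(FALSE, dm); pm[pvox] <- TRUE
      near_path <- edt(pm) <= 4 & comp == cc
      rmax <- max(redt[near_path])
      core <- near_path & redt >= rmax - 0.5
      r <- pmax(redt[core] - correction_vox, 0.5)
      rpath <- pmax(redt[pvox] - correction_vox, 0.5)
      dmean <- mean(2 * r) * voxel_size_um
      chans <- rbind(chans, data.frame(
        infarct_id = id, channel = ch, n_voxels = length(pvox),
        diam_mean_um = dmean, diam_min_um = min(2 * rpath) * voxel_size_um,
        reliable = dmean / voxel_size_um >= 2))
    }
  }
  per <- data.frame(id = ids, n_channels = 0L, mean_diam_um = NA_real_)
  if (nrow(chans)) {
    tab <- table(factor(chans$infarct_id, levels = ids))
    per$n_channels <- as.integer(tab)
    agg <- tapply(chans$diam_mean_um, factor(chans$infarct_id, levels = ids),
                  mean)
    per$mean_diam_um <- as.numeric(agg)
  }
  list(channels = chans, per_infarct = per)
}

#' Aggregate per-infarct records into a lobe summary
#'
#' @param records data.frame of per-infarct measurements with at least
#'   `V_um3`; optional columns `zone`, `psi`, `confluence` enrich the
#'   summary.
#' @param lobe_mask logical 3D array of the whole lobe (tissue) extent.
#' @param voxel_size_um voxel edge length in micrometres.
#' @return A `lobe_summary` list: `n_infarcts`, `total_volume_um3`,
#'   `lobe_volume_um3`, `volume_ratio`, `confluent_fraction`, and a
#'   `per_zone` data.frame (count fraction, total volume, sphericity
#'   median/IQR for zones I..III). An empty record set yields a zeroed
#'   summary.
#' @export
summarize_lobe <- function(records, lobe_mask, voxel_size_um) {
  lobe_v <- sum(lobe_mask) * voxel_size_um^3
  n <- nrow(records)
  per_zone <- data.frame(zone = 1:3, count_fraction = 0,
                         total_volume_um3 = 0, psi_median = NA_real_,
                         psi_iqr = NA_real_)
  if (n == 0L)
    return(structure(list(n_infarcts = 0L, total_volume_um3 = 0,
                          lobe_volume_um3 = lobe_v, volume_ratio = 0,
                          confluent_fraction = 0, per_zone = per_zone),
                     class = "lobe_summary"))
  tot <- sum(records$V_um3)
  confl <- if ("confluence" %in% names(records))
    mean(records$confluence == "confluent") else NA_real_
  if ("zone" %in% names(records)) {
    for (z in 1:3) {
      rz <- records[!is.na(records$zone) & records$zone == z, , drop = FALSE]
      per_zone$count_fraction[z] <- nrow(rz) / n
      per_zone$total_volume_um3[z] <- sum(rz$V_um3)
      if (nrow(rz) && "psi" %in% names(rz)) {
        keep <- if ("border" %in% names(rz)) !rz$border else TRUE
        if (any(keep)) {
          per_zone$psi_median[z] <- stats::median(rz$psi[keep])
          per_zone$psi_iqr[z] <- stats::IQR(rz$psi[keep])
        }
      }
    }
  }
  structure(list(n_infarcts = n, total_volume_um3 = tot,
                 lobe_volume_um3 = lobe_v,
                 volume_ratio = tot / lobe_v,
                 confluent_fraction = confl, per_zone = per_zone),
            class = "lobe_summary")
}

#' @export
print.lobe_summary <- function(x, ...) {
  cat(sprintf(
    "<lobe_summary> %d infarcts, total %.4g um^3 (%.3g%% of lobe)\n",
    x$n_infarcts, x$total_volume_um3, 100 * x$volume_ratio))
  if (!is.na(x$confluent_fraction))
    cat(sprintf("  confluent fraction %.3f\n", x$confluent_fraction))
  print(x$per_zone)
  invisible(x)
}
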