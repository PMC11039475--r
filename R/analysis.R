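# Measurement-side analysis flows shared by the pipeline driver, the
# tests and the acceptance script. These operate on grayscale volumes
# only (plus vessel seed points, which stand in for the manual seed
# placement of the original interactive workflow).

#' Deterministic vessel seed points from a truth grid
#'
#' Returns one seed per connected piece of each vessel tree (each tree
#' enters the lobe as several rooted trunks), the voxel lying deepest
#' inside the lumen, labelled 1 (portal) and 2 (central). This replaces
#' the manual seed clicks of an interactive segmentation.
#'
#' @param truth `phantom_truth`.
#' @param min_voxels ignore lumen pieces smaller than this.
#' @return integer matrix with columns `x, y, z, label`.
#' @export
vessel_seed_points <- function(truth, min_voxels = 30L) {
  out <- NULL
  d <- dims3(truth$labels)
  for (lbl in c(LBL_PORTAL, LBL_CENTRAL)) {
    m <- truth$labels == lbl
    if (!any(m)) next
    comp <- label_array(m, 26L)
    depth <- edt(!m)
    for (cc in seq_len(max(comp))) {
      sel <- comp == cc
      if (sum(sel) < min_voxels) next
      dloc <- depth
      dloc[!sel] <- 0
      w <- which.max(dloc)
      out <- rbind(out, cbind(ind_to_xyz(w, d), label = lbl))
    }
  }
  out
}

#' Full measurement chain for a lobe-scale grayscale volume
#'
#' Region-grows the portal and central trees from the given seeds,
#' threshold-segments the infarcts from the remaining voxels, labels the
#' components, builds the equal-volume acinus zonation from the grown
#' central tree, and measures every infarct (volume, surface,
#' sphericity, zone, confluence).
#'
#' @param volume grayscale [voxel_volume].
#' @param seeds seed matrix as from [vessel_seed_points()].
#' @param config a [segmentation_config()].
#' @param h_voxels,min_core_fraction confluence-rule parameters, see
#'   [classify_confluence()].
#' @return list: `vessel_labels`, `infarct_labels`, `records` (per-infarct
#'   data.frame), `zones`, `summary` (a `lobe_summary`).
#' @export
analyze_lobe_volume <- function(volume, seeds,
                                config = segmentation_config(
                                  grow_tolerance = 15),
                                h_voxels = 2, min_core_fraction = 0.1) {
  vs <- volume$voxel_size_um
  cfg <- config
  cfg$vessel_seeds <- seeds
  vessels <- segment_vessels_region_growing(volume, cfg)
  imask <- segment_infarcts_threshold(volume, config,
                                      vessel_mask = vessels > 0L)
  # vessel lumina are darker than infarcts; a second two-class split of
  # the sub-threshold voxels reclaims vessel fragments the seeded growth
  # could not reach (e.g. branches occluded by a crossing tree)
  if (any(imask)) {
    thr2 <- auto_threshold(volume$data[imask])
    if (!is.na(thr2)) {
      lum <- imask & volume$data < thr2
      imask <- imask & !lum
      near_portal <- edt(vessels == LBL_PORTAL) <= edt(vessels == LBL_CENTRAL)
      vessels[lum & near_portal] <- LBL_PORTAL
      vessels[lum & !near_portal] <- LBL_CENTRAL
    }
  }
  portal <- vessels == LBL_PORTAL
  central <- vessels == LBL_CENTRAL
  lc <- label_components(imask, vs, config)
  zones <- equal_volume_zonation(parenchyma = vessels == 0L,
                                 central_veins = central,
                                 portal_veins = portal,
                                 voxel_size_um = vs)
  records <- measure_components(lc$labels, vs)
  if (nrow(records)) {
    za <- assign_infarct_zones(lc$labels, zones)
    records$zone <- za$zone[match(records$id, za$id)]
    records$confluence <- vapply(records$id, function(id)
      classify_confluence(lc$labels == id, vs, h_voxels,
                          min_core_fraction)$confluence, "")
  }
  summary <- summarize_lobe(records, array(TRUE, dim = dim(volume$data)),
                            vs)
  list(vessel_labels = vessels, infarct_labels = lc$labels,
       records = records, zones = zones, summary = summary)
}

#' Full measurement chain for a submicron grayscale volume
#'
#' Classifies every voxel to the nearest tissue intensity (parenchyma,
#' infarct, sinusoid, lumen), separates large lumen components (vessel
#' trunks) from small ones (candidate microchannels), labels the
#' infarcts and runs the microchannel detector.
#'
#' @param volume grayscale [voxel_volume].
#' @param gray_levels named class intensities (as in the phantom
#'   presets).
#' @param min_component_um3 infarct size filter; the default admits the
#'   smallest submicron-scale lesions.
#' @param trunk_radius_vox lumen tubes with interior radius above this
#'   (voxels) are treated as vein trunks, not channels.
#' @param ... passed to [detect_microchannels()].
#' @return list: `infarct_labels`, `sinusoid_mask`, `lumen_mask`,
#'   `records`, `channels`, `per_infarct`.
#' @export
analyze_submicron_volume <- function(volume,
                                     gray_levels = .default_gray_levels,
                                     min_component_um3 = 40,
                                     trunk_radius_vox = 4.5, ...) {
  vs <- volume$voxel_size_um
  levels <- c(parenchyma = unname(gray_levels[["parenchyma"]]),
              infarct = unname(gray_levels[["infarct"]]),
              sinusoid = unname(gray_levels[["sinusoid"]]),
              lumen = min(gray_levels[["portal"]], gray_levels[["central"]],
                          gray_levels[["channel"]]))
  # no majority smoothing: the 3x3x3 filter would erode the one-voxel
  # surface layer of ~5-voxel-diameter microchannels
  cl <- classify_tissue(volume, levels, smooth = FALSE)
  sinusoid <- cl == 3L
  lumen_all <- cl == 4L
  infarct <- cl == 2L
  cfg <- segmentation_config(min_component_um3 = min_component_um3)
  lc <- label_components(infarct, vs, cfg)
  # vein trunks are an order of magnitude wider than microchannels:
  # remove lumen voxels belonging to any tube whose interior radius
  # exceeds the trunk cutoff, leaving only thin (channel-calibre) lumina
  lumen <- lumen_all
  if (any(lumen_all)) {
    rl <- edt(!lumen_all)
    trunk_core <- lumen_all & rl >= trunk_radius_vox
    if (any(trunk_core))
      lumen <- lumen_all & !(edt(trunk_core) <= trunk_radius_vox + 2.5)
  }
  det <- detect_microchannels(lc$labels, sinusoid, lumen, vs, ...)
  records <- measure_components(lc$labels, vs)
  list(infarct_labels = lc$labels, sinusoid_mask = sinusoid,
       lumen_mask = lumen, records = records,
       channels = det$channels, per_infarct = det$per_infarct)
}

#' Smallest reliably detectable sphere after a simulated acquisition
#'
#' Embeds pairs of spheres of the given diameters (in voxels) in a
#' cylindrical soft-tissue specimen, simulates the full lobe-scale
#' acquisition (phase-contrast projection formation with photon noise,
#' flat/dark correction, single-distance phase retrieval, filtered
#' back-projection), threshold-segments the reconstruction and checks
#' which spheres are recovered near their true centres. The detection
#' threshold is the midpoint of the known parenchyma and infarct
#' attenuation coefficients.
#'
#' @param seeds integer vector of noise seeds (one acquisition each).
#' @param diameters_vox sphere diameters in voxels.
#' @param grid cubic grid edge (voxels).
#' @param n_angles projections per acquisition.
#' @param noise_photons photon budget per pixel.
#' @param optics per-class optical constants.
#' @return list with the per-diameter detection-rate vector `rates`
#'   (named by diameter in micrometres) and
#'   `smallest_reliable_um`, the smallest diameter detected in at least
#'   90% of the acquisitions.
#' @export
sphere_detectability <- function(seeds, diameters_vox = 2:6, grid = 64L,
                                 n_angles = 200L, noise_photons = 20000,
                                 optics = tissue_optics()) {
  n <- grid
  vs <- 3.25
  x <- seq_len(n)
  c0 <- (n + 1) / 2
  rcyl <- sqrt(outer((x - c0)^2, (x - c0)^2, "+"))
  cyl <- array(rep(rcyl <= 0.45 * n, n), dim = c(n, n, n))
  delta <- array(0, dim = c(n, n, n)); beta <- array(0, dim = c(n, n, n))
  delta[cyl] <- optics$parenchyma["delta"]
  beta[cyl] <- optics$parenchyma["beta"]
  diams <- rep(diameters_vox, each = 2L)
  ang <- (seq_along(diams) - 1) * 2 * pi / length(diams)
  pos <- cbind(c0 + 0.26 * n * cos(ang), c0 + 0.26 * n * sin(ang),
               rep(c(0.38, 0.62) * n, length.out = length(diams)))
  for (i in seq_along(diams)) {
    cc <- pos[i, ]
    rr <- sqrt(outer(outer((x - cc[1])^2, (x - cc[2])^2, "+"),
                     (x - cc[3])^2, "+"))
    m <- rr <= diams[i] / 2
    delta[m] <- optics$infarct["delta"]
    beta[m] <- optics$infarct["beta"]
  }
  geom <- beam_geometry(16, 28, vs, n_angles)
  mu_par <- 4 * pi * optics$parenchyma["beta"] / geom$wavelength_um
  mu_inf <- 4 * pi * optics$infarct["beta"] / geom$wavelength_um
  interior <- array(rep(rcyl <= 0.4 * n, n), dim = c(n, n, n))
  hits <- matrix(0, length(seeds), length(diameters_vox))
  for (s in seq_along(seeds)) {
    ps <- simulate_projections(optical_phantom(delta, beta, vs), geom,
                               noise_photons = noise_photons,
                               seed = seeds[s])
    rec <- fbp_reconstruct(phase_retrieve(flat_dark_correct(ps), 1000))
    lvl <- stats::median(rec$data[interior])
    # cutoff at 40% of the class contrast below the parenchyma level:
    # partial volume and the detector PSF leave small lesions with only
    # about half of the nominal contrast at their centre
    mask <- rec$data < lvl - 0.4 * (mu_par - mu_inf) & interior
    lc <- label_components(mask, vs,
                           segmentation_config(min_component_um3 = 2 * vs^3))
    for (i in seq_along(diams)) {
      cc <- pos[i, ]
      hit <- FALSE
      if (nrow(lc$table)) {
        dd <- sqrt((lc$table$cx_um / vs + 1 - cc[1])^2 +
                     (lc$table$cy_um / vs + 1 - cc[2])^2 +
                     (lc$table$cz_um / vs + 1 - cc[3])^2)
        hit <- any(dd < 2.5)
      }
      k <- match(diams[i], diameters_vox)
      hits[s, k] <- hits[s, k] + hit / 2
    }
  }
  rates <- colMeans(hits)
  names(rates) <- sprintf("%.2f", diameters_vox * vs)
  reliable <- which(rates >= 0.9)
  list(rates = rates,
       smallest_reliable_um =
         if (length(reliable)) diameters_vox[min(reliable)] * vs else NA)
}
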