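#' Segmentation configuration
#'
#' @param infarct_threshold `"auto"` (two-class Gaussian-mixture split of
#'   the non-vessel intensity histogram) or a fixed numeric cutoff; voxels
#'   strictly below it are candidate infarct.
#' @param vessel_seeds integer matrix with columns `x, y, z, label`
#'   giving region-growing seeds and their target labels.
#' @param grow_tolerance maximum absolute deviation from the running
#'   seed-region mean accepted during region growing.
#' @param connectivity 6, 18 or 26.
#' @param min_component_um3 components smaller than this physical volume
#'   are dropped; the default is the volume of a 10 um diameter sphere,
#'   the smallest infarct distinguishable at the lobe scale.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(infarct_threshold = "auto",
                                vessel_seeds = NULL,
                                grow_tolerance = 10,
                                connectivity = 26L,
                                min_component_um3 = 4 / 3 * pi * 5^3) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (min_component_um3 < 0) stop("min_component_um3 must be >= 0")
  structure(list(infarct_threshold = infarct_threshold,
                 vessel_seeds = vessel_seeds,
                 grow_tolerance = grow_tolerance,
                 connectivity = as.integer(connectivity),
                 min_component_um3 = min_component_um3),
            class = "segmentation_config")
}

# Two-class intensity split by a two-component Gaussian mixture (EM with
# free weights and variances, initialised from the histogram extremes).
# Unlike the plain Otsu rule, the free mixing weight keeps the split
# honest when the dark class holds well under 1% of the voxels, which is
# the typical early-day infarct fraction. Returns the decision boundary
# between the two fitted components, or NA when the fit is degenerate
# (effectively unimodal data).
auto_threshold <- function(values, max_sample = 200000L, max_iter = 100L) {
  rng <- range(values)
  if (diff(rng) == 0) return(NA_real_)
  if (length(values) > max_sample)
    values <- values[seq(1L, length(values),
                         length.out = max_sample)]
  mu <- c(stats::quantile(values, 0.001), stats::median(values))
  s2 <- rep(stats::var(values) / 4, 2)
  w <- c(0.05, 0.95)
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(values, mu[1], sqrt(s2[1]))
    d2 <- w[2] * stats::dnorm(values, mu[2], sqrt(s2[2]))
    g <- d1 / pmax(d1 + d2, 1e-300)
    w_new <- c(mean(g), 1 - mean(g))
    if (w_new[1] < 1e-6 || w_new[2] < 1e-6) return(NA_real_)
    mu_new <- c(sum(g * values) / sum(g),
                sum((1 - g) * values) / sum(1 - g))
    s2_new <- c(sum(g * (values - mu_new[1])^2) / sum(g),
                sum((1 - g) * (values - mu_new[2])^2) / sum(1 - g))
    s2_new <- pmax(s2_new, 1e-12)
    done <- max(abs(mu_new - mu)) < 1e-6 * diff(rng)
    mu <- mu_new; s2 <- s2_new; w <- w_new
    if (done) break
  }
  if (mu[1] > mu[2]) { mu <- rev(mu); s2 <- rev(s2); w <- rev(w) }
  # degenerate when the components are not separated
  if ((mu[2] - mu[1]) < 2 * sqrt(max(s2))) return(NA_real_)
  # decision boundary: equal posterior density between the components
  # (closed form; stable even when the fitted variances are tiny)
  A <- 1 / s2[1] - 1 / s2[2]
  B <- -2 * (mu[1] / s2[1] - mu[2] / s2[2])
  C <- mu[1]^2 / s2[1] - mu[2]^2 / s2[2] -
    (2 * log(w[1] / w[2]) - log(s2[1] / s2[2]))
  roots <- if (abs(A) < 1e-12 * abs(B)) {
    -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0)
    else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  roots <- roots[roots > mu[1] & roots < mu[2]]
  if (length(roots) == 0L) mean(mu) else roots[1]
}

#' Threshold segmentation of bile infarcts
#'
#' Infarcts have lower density than healthy parenchyma and appear darker,
#' so the mask is all voxels below the cutoff, minus any voxels already
#' claimed by vessel masks (vessels win conflicts: infarcts are
#' parenchymal lesions). In `"auto"` mode the cutoff is a two-class
#' Gaussian-mixture split computed over non-vessel voxels only.
#'
#' @param volume a [voxel_volume].
#' @param config a [segmentation_config()].
#' @param vessel_mask optional logical array of voxels excluded as
#'   vessel lumina.
#' @return logical mask with the chosen cutoff attached as attribute
#'   `"threshold"`. A degenerate (single-valued) histogram in auto mode
#'   yields an empty mask with a warning.
#' @export
segment_infarcts_threshold <- function(volume, config = segmentation_config(),
                                       vessel_mask = NULL) {
  v <- volume$data
  if (!all(is.finite(v))) stop("volume must be finite-valued")
  keep <- if (is.null(vessel_mask)) rep(TRUE, length(v)) else !vessel_mask
  thr <- config$infarct_threshold
  if (identical(thr, "auto")) {
    thr <- auto_threshold(v[keep])
    if (is.na(thr)) {
      warning("degenerate intensity histogram: auto threshold undefined, ",
              "returning empty mask")
      mask <- array(FALSE, dim = dim(v))
      attr(mask, "threshold") <- NA_real_
      return(mask)
    }
  }
  mask <- array(v < thr, dim = dim(v))
  if (!is.null(vessel_mask)) mask <- mask & !vessel_mask
  attr(mask, "threshold") <- thr
  mask
}

#' Region-growing vessel segmentation
#'
#' Breadth-first growth from each seed, accepting 26-neighbours whose
#' intensity lies within `grow_tolerance` of the running mean of the
#' region grown so far. Seeds are processed in order; the first label to
#' claim a voxel keeps it and cross-label conflicts are counted in
#' attribute `"conflicts"`.
#'
#' @param volume a [voxel_volume].
#' @param config a [segmentation_config()] with `vessel_seeds` set.
#' @return integer label array.
#' @export
segment_vessels_region_growing <- function(volume, config) {
  seeds <- config$vessel_seeds
  if (is.null(seeds) || nrow(seeds) == 0L)
    stop("config$vessel_seeds is required")
  d <- dims3(volume$data)
  sxyz <- as.matrix(seeds[, 1:3, drop = FALSE])
  if (any(sxyz < 1) || any(sxyz > matrix(d, nrow(sxyz), 3, byrow = TRUE)))
    stop("seed coordinates outside the volume")
  res <- cpp_region_grow(as.double(volume$data), d,
                         sxyz - 1L, as.integer(seeds[, 4]),
                         config$grow_tolerance)
  out <- array(res$labels, dim = d)
  attr(out, "conflicts") <- res$conflicts
  out
}

#' Label connected components and tabulate them
#'
#' Components are found under the configured connectivity, filtered by
#' the physical minimum volume, and relabelled 1..k in order of
#' decreasing volume.
#'
#' @param mask logical array.
#' @param voxel_size_um voxel edge length in micrometres.
#' @param config a [segmentation_config()].
#' @return list with integer array `labels` and data.frame `table`
#'   (`id`, `n_voxels`, `volume_um3`, centroid in um).
#' @export
label_components <- function(mask, voxel_size_um,
                             config = segmentation_config()) {
  d <- dims3(mask)
  raw <- label_array(mask, config$connectivity)
  k <- max(raw)
  empty <- list(labels = array(0L, dim = d),
                table = data.frame(id = integer(0), n_voxels = integer(0),
                                   volume_um3 = numeric(0),
                                   cx_um = numeric(0), cy_um = numeric(0),
                                   cz_um = numeric(0)))
  if (k == 0L) return(empty)
  sizes <- tabulate(raw[raw > 0L], nbins = k)
  keep <- which(sizes * voxel_size_um^3 >= config$min_component_um3)
  if (length(keep) == 0L) return(empty)
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  remap <- integer(k)
  remap[ord] <- seq_along(ord)
  labels <- array(0L, dim = d)
  nz <- raw > 0L
  labels[nz] <- remap[raw[nz]]
  tab <- do.call(rbind, lapply(seq_along(ord), function(i) {
    s <- ind_to_xyz(which(labels == i), d)
    data.frame(id = i, n_voxels = nrow(s),
               volume_um3 = nrow(s) * voxel_size_um^3,
               cx_um = (mean(s[, 1]) - 1) * voxel_size_um,
               cy_um = (mean(s[, 2]) - 1) * voxel_size_um,
               cz_um = (mean(s[, 3]) - 1) * voxel_size_um)
  }))
  list(labels = labels, table = tab)
}

#' Nearest-class tissue classification of a rendered volume
#'
#' Maximum-likelihood labelling of a piecewise-constant volume under
#' additive Gaussian noise: each voxel is assigned the tissue class with
#' the nearest expected intensity, optionally followed by a 3x3x3
#' majority filter to remove isolated misclassified voxels.
#'
#' @param volume a [voxel_volume].
#' @param class_levels named numeric vector of expected intensities.
#' @param smooth apply the majority filter.
#' @return integer array of class indices (1-based into
#'   `names(class_levels)`), with the names attached as attribute
#'   `"classes"`.
#' @export
classify_tissue <- function(volume, class_levels, smooth = TRUE) {
  v <- volume$data
  d <- dims3(v)
  lv <- as.numeric(class_levels)
  cl <- array(1L, dim = d)
  best <- abs(v - lv[1])
  for (i in seq_along(lv)[-1]) {
    di <- abs(v - lv[i])
    swap <- di < best
    cl[swap] <- i
    best[swap] <- di[swap]
  }
  if (smooth)
    cl <- array(cpp_mode_filter(as.integer(cl), d, length(lv)), dim = d)
  attr(cl, "classes") <- names(class_levels)
  cl
}
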