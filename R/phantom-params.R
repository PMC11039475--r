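# Day presets for the synthetic liver phantoms.
#
# The post-ligation day presets encode the study conditions the analysis is
# validated against: infarct counts rise close to linearly, total infarct
# volume grows near-exponentially with a 9-fold day-7/day-1 multiplier,
# the confluent fraction rises 8% -> 25%, infarct placement shifts from a
# zone-I majority on day 1 to zone III holding the largest share on day 7,
# and microchannel counts per infarct average 1.86 / 2.47 / 3.38 / 5.47
# with a 3.41 um channel diameter. Counts are referenced to a 128^3 grid
# and scaled with grid volume. Radius ranges are calibrated so that the
# EXPECTED total volume (accounting for cluster-overlap and surface-
# roughness volume inflation) follows the multipliers (1, 2.3, 4.9, 9);
# see the methods vignette for the calibration.

.day_levels <- c("control", "1", "3", "5", "7")

.lobe_presets <- data.frame(
  day = .day_levels,
  n_infarcts_ref = c(0L, 12L, 18L, 25L, 32L),
  confluent_fraction = c(0, 0.08, 0.15, 0.21, 0.25),
  w_zone1 = c(NA, 0.65, 0.50, 0.32, 0.18),
  w_zone2 = c(NA, 0.22, 0.28, 0.33, 0.34),
  w_zone3 = c(NA, 0.13, 0.22, 0.35, 0.48),
  r_min_um = c(NA, 13.000, 14.642, 16.505, 18.248),
  r_max_um = c(NA, 26.000, 29.284, 33.010, 36.495),
  sphericity_roughness = c(0, 0.06, 0.10, 0.14, 0.18),
  microchannel_count_mean = c(0, 1.86, 2.47, 3.38, 5.47),
  stringsAsFactors = FALSE)

.submicron_presets <- data.frame(
  day = .day_levels,
  n_infarcts_ref = c(0L, 25L, 25L, 25L, 25L),
  confluent_fraction = c(0, 0, 0, 0, 0),
  w_zone1 = c(NA, 0.65, 0.50, 0.32, 0.18),
  w_zone2 = c(NA, 0.22, 0.28, 0.33, 0.34),
  w_zone3 = c(NA, 0.13, 0.22, 0.35, 0.48),
  r_min_um = c(NA, 3.25, 3.60, 3.90, 4.20),
  r_max_um = c(NA, 6.50, 7.20, 7.80, 8.40),
  sphericity_roughness = c(0, 0.06, 0.10, 0.14, 0.18),
  microchannel_count_mean = c(0, 1.86, 2.47, 3.38, 5.47),
  stringsAsFactors = FALSE)

#' Day preset tables for the synthetic phantoms
#'
#' @param scale `"lobe"` (3.25 um voxels, whole-lobe statistics) or
#'   `"submicron"` (0.65 um voxels, lobule volume of interest with
#'   sinusoids and microchannels).
#' @return data.frame of per-day generator presets.
#' @export
phantom_presets <- function(scale = c("lobe", "submicron")) {
  scale <- match.arg(scale)
  if (scale == "lobe") .lobe_presets else .submicron_presets
}

.default_gray_levels <- c(parenchyma = 120, infarct = 75, portal = 25,
                          central = 25, sinusoid = 45, channel = 25)

#' Phantom generator parameters
#'
#' Assembles the full parameter set for one synthetic liver volume. All
#' fields default from the day/scale preset ([phantom_presets()]) and can
#' be overridden individually.
#'
#' @param day post-ligation day label: `"control"`, `"1"`, `"3"`, `"5"`
#'   or `"7"`.
#' @param scale `"lobe"` or `"submicron"`.
#' @param grid_shape voxel counts per axis (length 3, or a scalar for a
#'   cube).
#' @param seed RNG seed; every generator stage derives its own sub-seed
#'   from it, so identical parameters give bit-identical phantoms.
#' @param n_infarcts,confluent_fraction,zone_placement_weights,
#'   microchannel_count_mean,microchannel_diameter_um,
#'   infarct_radius_um_range,sphericity_roughness,gray_levels,noise_sd
#'   optional overrides of the preset values.
#' @param voxel_size_um defaults to 3.25 (lobe) or 0.65 (submicron).
#' @return A validated `phantom_params` list.
#' @export
phantom_params <- function(day = "1", scale = c("lobe", "submicron"),
                           grid_shape = c(128L, 128L, 128L), seed = 1L,
                           voxel_size_um = NULL, n_infarcts = NULL,
                           confluent_fraction = NULL,
                           zone_placement_weights = NULL,
                           microchannel_count_mean = NULL,
                           microchannel_diameter_um = 3.41,
                           infarct_radius_um_range = NULL,
                           sphericity_roughness = NULL,
                           gray_levels = .default_gray_levels,
                           noise_sd = 5) {
  scale <- match.arg(scale)
  day <- match.arg(as.character(day), .day_levels)
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  grid_shape <- as.integer(grid_shape)
  pre <- phantom_presets(scale)
  pre <- pre[pre$day == day, ]
  voxel_size_um <- voxel_size_um %||% if (scale == "lobe") 3.25 else 0.65
  n_ref <- pre$n_infarcts_ref
  n_infarcts <- as.integer(n_infarcts %||% (if (n_ref == 0L) 0L else
    max(1L, round(n_ref * prod(grid_shape) / 128^3))))
  confluent_fraction <- confluent_fraction %||% pre$confluent_fraction
  zone_placement_weights <- zone_placement_weights %||%
    c(pre$w_zone1, pre$w_zone2, pre$w_zone3)
  microchannel_count_mean <- microchannel_count_mean %||%
    pre$microchannel_count_mean
  infarct_radius_um_range <- infarct_radius_um_range %||%
    c(pre$r_min_um, pre$r_max_um)
  sphericity_roughness <- sphericity_roughness %||% pre$sphericity_roughness

  p <- structure(list(
    day = day, scale = scale, grid_shape = grid_shape,
    voxel_size_um = voxel_size_um, n_infarcts = n_infarcts,
    zone_placement_weights = zone_placement_weights,
    confluent_fraction = confluent_fraction,
    microchannel_count_mean = microchannel_count_mean,
    microchannel_diameter_um = microchannel_diameter_um,
    infarct_radius_um_range = infarct_radius_um_range,
    sphericity_roughness = sphericity_roughness,
    gray_levels = gray_levels, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "phantom_params")
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (p$n_infarcts > 0L) {
    w <- p$zone_placement_weights
    if (length(w) != 3L || any(is.na(w)) ||
        abs(sum(w) - 1) > 1e-9 || any(w < 0))
      stop("zone_placement_weights must be 3 non-negative values summing to 1")
    rr <- p$infarct_radius_um_range
    if (length(rr) != 2L || any(!is.finite(rr)) || any(rr <= 0) ||
        rr[1] > rr[2])
      stop("infarct_radius_um_range must be a positive (min, max) pair")
  }
  if (p$confluent_fraction < 0 || p$confluent_fraction > 1)
    stop("confluent_fraction must be in [0, 1]")
  if (p$voxel_size_um <= 0 || p$microchannel_diameter_um <= 0)
    stop("all physical sizes must be positive")
  if (p$noise_sd < 0) stop("noise_sd must be non-negative")
  invisible(p)
}

#' @export
print.phantom_params <- function(x, ...) {
  cat(sprintf("<phantom_params> day %s, %s scale, %s grid, %.3g um/voxel\n",
              x$day, x$scale, paste(x$grid_shape, collapse = "x"),
              x$voxel_size_um))
  cat(sprintf("  %d infarcts, confluent fraction %.2f, seed %d\n",
              x$n_infarcts, x$confluent_fraction, x$seed))
  invisible(x)
}

# Label codes used in the truth grid.
LBL_PORTAL <- 1L
LBL_CENTRAL <- 2L
LBL_SINUSOID <- 3L
LBL_INFARCT0 <- 10L    # infarct unit u has code LBL_INFARCT0 + u
LBL_CHANNEL0 <- 1000L  # channel c has code LBL_CHANNEL0 + c
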