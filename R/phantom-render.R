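#' Render a phantom truth grid to grayscale
#'
#' Maps every tissue class to its preset intensity and adds Gaussian
#' noise. Infarcts render darker than the surrounding parenchyma (they
#' are less dense tissue) and vessel/channel lumina darkest, matching the
#' contrast polarity of phase-contrast CT slices of cholestatic liver.
#'
#' @param truth `phantom_truth` grid.
#' @param params the generating [phantom_params()] (supplies
#'   `gray_levels`, `noise_sd` and the rendering sub-seed).
#' @return A [voxel_volume] of intensities.
#' @export
render_grayscale <- function(truth, params) {
  gl <- params$gray_levels
  labels <- truth$labels
  classes <- c("parenchyma",
               if (any(labels == LBL_PORTAL)) "portal",
               if (any(labels == LBL_CENTRAL)) "central",
               if (any(labels == LBL_SINUSOID)) "sinusoid",
               if (any(labels >= LBL_INFARCT0 & labels < LBL_CHANNEL0))
                 "infarct",
               if (any(labels >= LBL_CHANNEL0)) "channel")
  missing <- setdiff(classes, names(gl))
  if (length(missing))
    stop("gray_levels is missing class '", missing[1], "'")
  v <- array(gl[["parenchyma"]], dim = dim(labels))
  if ("portal" %in% classes) v[labels == LBL_PORTAL] <- gl[["portal"]]
  if ("central" %in% classes) v[labels == LBL_CENTRAL] <- gl[["central"]]
  if ("sinusoid" %in% classes) v[labels == LBL_SINUSOID] <- gl[["sinusoid"]]
  if ("infarct" %in% classes)
    v[labels >= LBL_INFARCT0 & labels < LBL_CHANNEL0] <- gl[["infarct"]]
  if ("channel" %in% classes)
    v[labels >= LBL_CHANNEL0] <- gl[["channel"]]
  if (params$noise_sd > 0)
    v <- v + with_seed(stage_seed(params$seed, 404L),
                       array(stats::rnorm(length(v), 0, params$noise_sd),
                             dim = dim(v)))
  voxel_volume(v, params$voxel_size_um)
}

#' Generate a complete synthetic liver phantom
#'
#' Runs the full generator: vascular trees, equal-volume acinus zonation
#' of the resulting parenchyma, infarct placement, microchannel placement
#' (submicron scale only) and grayscale rendering. Identical parameters
#' (including the seed) give bit-identical output.
#'
#' @param params a [phantom_params()] object.
#' @param render if `FALSE`, skip the grayscale rendering.
#' @return A `liver_phantom` list: `params`, `truth`, `zones`, `volume`.
#' @export
generate_phantom <- function(params, render = TRUE) {
  truth <- build_vessel_trees(params)
  zones <- equal_volume_zonation(
    parenchyma = truth$labels == 0L,
    central_veins = truth$labels == LBL_CENTRAL,
    portal_veins = truth$labels == LBL_PORTAL,
    voxel_size_um = params$voxel_size_um)
  truth <- place_infarcts(params, truth, zones)
  if (params$scale == "submicron" && params$microchannel_count_mean > 0 &&
      nrow(truth$infarct_table) > 0)
    truth <- place_microchannels(params, truth)
  volume <- if (render) render_grayscale(truth, params) else NULL
  structure(list(params = params, truth = truth, zones = zones,
                 volume = volume),
            class = "liver_phantom")
}

#' @export
print.liver_phantom <- function(x, ...) {
  print(x$params)
  print(x$truth)
  invisible(x)
}

#' Write phantom truth to disk
#'
#' Writes the label grid as a 16-bit TIFF stack with a JSON sidecar
#' (voxel size, day, seed, label dictionary) and the infarct/channel
#' truth tables as CSV.
#'
#' @param truth `phantom_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lv <- voxel_volume(truth$labels, truth$voxel_size_um)
  write_volume(lv, file.path(dir, "labels.tif"), metadata = list(
    day = truth$day, seed = truth$seed, scale = truth$scale,
    label_dictionary = list(parenchyma = 0, portal = LBL_PORTAL,
                            central = LBL_CENTRAL, sinusoid = LBL_SINUSOID,
                            infarct_base = LBL_INFARCT0,
                            channel_base = LBL_CHANNEL0)))
  it <- truth$infarct_table
  utils::write.csv(
    it[, c("infarct_id", "cluster_id", "origin_zone", "volume_um3",
           "n_channels", "channel_diam_um")],
    file.path(dir, "infarcts.csv"), row.names = FALSE)
  utils::write.csv(truth$channel_table, file.path(dir, "channels.csv"),
                   row.names = FALSE)
  invisible(dir)
}
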