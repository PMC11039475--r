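# Miniature propagation-based phase-contrast CT.
#
# The sample is a complex refractive index field n = 1 - delta + i*beta.
# A parallel monochromatic beam accumulates phase
# phi = -(2*pi/lambda) * integral(delta) and amplitude
# exp(-(2*pi/lambda) * integral(beta)) along each ray; the exit wave is
# propagated to the detector with the paraxial Fresnel kernel and its
# intensity recorded. Soft tissue has delta up to three orders of
# magnitude larger than beta, which is what makes the propagation fringes
# (and hence phase contrast) visible at all.

fftfreq <- function(n) {
  c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / n
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

#' Acquisition geometry
#'
#' @param energy_keV photon energy; the wavelength is derived as
#'   `1.23984193e-4 / energy_keV` micrometres.
#' @param distance_cm sample-to-detector propagation distance.
#' @param pixel_size_um detector pixel size (= reconstruction voxel size).
#' @param n_angles projections spread uniformly over 180 degrees.
#' @param psf_fwhm_px Gaussian detector blur FWHM in pixels (0 = ideal).
#' @return A `beam_geometry` list (with `wavelength_um` filled in).
#' @export
beam_geometry <- function(energy_keV, distance_cm, pixel_size_um, n_angles,
                          psf_fwhm_px = 1) {
  if (distance_cm <= 0) stop("geometry error: distance must be positive")
  if (energy_keV <= 0) stop("geometry error: energy must be positive")
  structure(list(energy_keV = energy_keV,
                 wavelength_um = 1.23984193e-4 / energy_keV,
                 distance_cm = distance_cm,
                 pixel_size_um = pixel_size_um,
                 n_angles = as.integer(n_angles),
                 psf_fwhm_px = psf_fwhm_px),
            class = "beam_geometry")
}

#' Acquisition presets for the two imaging scales
#'
#' Lobe scale: 16 keV, 28 cm, 3.25 um pixels, 1200 projections.
#' Submicron scale: 14 keV, 16 cm, 0.65 um pixels, 900 projections.
#'
#' @param scale `"lobe"` or `"submicron"`.
#' @param n_angles optionally override the projection count (the presets
#'   match the full acquisitions; reduced counts are often enough for
#'   small simulated grids).
#' @return A [beam_geometry()].
#' @export
geometry_preset <- function(scale = c("lobe", "submicron"),
                            n_angles = NULL) {
  scale <- match.arg(scale)
  if (scale == "lobe")
    beam_geometry(16, 28, 3.25, n_angles %||% 1200L)
  else
    beam_geometry(14, 16, 0.65, n_angles %||% 900L)
}

#' Optical phantom (delta/beta volume pair)
#'
#' @param delta,beta non-negative 3D arrays of the refractive index
#'   decrement and attenuation index, same shape.
#' @param voxel_size_um voxel edge length in micrometres.
#' @return An `optical_phantom` list.
#' @export
optical_phantom <- function(delta, beta, voxel_size_um) {
  if (!identical(dim(delta), dim(beta)))
    stop("delta and beta grids must have the same shape")
  if (min(delta) < 0 || min(beta) < 0)
    stop("delta and beta must be non-negative")
  structure(list(delta = delta, beta = beta,
                 voxel_size_um = voxel_size_um),
            class = "optical_phantom")
}

#' Soft-tissue optical constants used by the simulator
#'
#' Invented but physically plausible fixtures with delta/beta = 1000
#' (single-material duality): dehydrated liver parenchyma, the less dense
#' infarcted tissue, and vessel lumina.
#'
#' @return named list of `(delta, beta)` pairs.
#' @export
tissue_optics <- function() {
  list(parenchyma = c(delta = 2.0e-7, beta = 2.0e-10),
       infarct = c(delta = 1.7e-7, beta = 1.7e-10),
       lumen = c(delta = 1.0e-7, beta = 1.0e-10))
}

#' Simulate phase-contrast projections
#'
#' For each angle the delta and beta volumes are line-integrated, the
#' exit wave is propagated to the detector by the paraxial Fresnel
#' kernel, the intensity is blurred by the detector PSF, modulated by a
#' smooth illumination profile, scaled to `noise_photons` counts and
#' Poisson-sampled (0 = noiseless). Synthetic flat fields (sample out of
#' beam) and dark fields (shutter closed) are emitted alongside.
#'
#' @param phantom an [optical_phantom()].
#' @param geometry a [beam_geometry()].
#' @param noise_photons mean photon count per pixel in the flat beam;
#'   0 disables noise.
#' @param n_flat,n_dark numbers of flat/dark frames.
#' @param dark_level mean dark counts per pixel.
#' @param seed RNG seed for the Poisson noise.
#' @param supersample lateral oversampling factor of the wave-optics
#'   grid. The exit-wave phase varies by several radians per pixel at
#'   sharp object edges; computing the Fresnel propagation on a finer
#'   grid and binning the intensity back to detector pixels keeps the
#'   simulation faithful there.
#' @return A `projection_set`: raw `frames` (n_det x nz x n_angles),
#'   `flats`, `darks`, `angles`, `geometry`, `corrected = FALSE`.
#' @export
simulate_projections <- function(phantom, geometry, noise_photons = 0,
                                 n_flat = 10L, n_dark = 5L,
                                 dark_level = 100, seed = 1L,
                                 supersample = 2L) {
  d <- dims3(phantom$delta)
  if (d[1] != d[2])
    stop("field-of-view error: phantom slices must be square")
  vs <- phantom$voxel_size_um
  if (abs(vs - geometry$pixel_size_um) > 1e-9)
    stop("phantom voxel size must equal the detector pixel size")
  lambda <- geometry$wavelength_um
  D_um <- geometry$distance_cm * 1e4
  na <- geometry$n_angles
  angles <- seq(0, pi, length.out = na + 1L)[seq_len(na)]
  nd <- d[1]; nz <- d[3]
  ss <- max(1L, as.integer(supersample))
  nds <- ss * nd; nzs <- ss * nz

  pd <- array(cpp_forward_project(as.double(phantom$delta), d, angles, 0.5,
                                  nds, 1 / ss),
              dim = c(nds, na, nz)) * vs
  pb <- array(cpp_forward_project(as.double(phantom$beta), d, angles, 0.5,
                                  nds, 1 / ss),
              dim = c(nds, na, nz)) * vs

  # linear z-upsampling and ss x ss intensity binning operators
  if (ss > 1L) {
    u <- pmin(pmax(((seq_len(nzs)) - 0.5) / ss + 0.5, 1), nz)
    lo <- pmin(floor(u), nz - 1L); fr_ <- u - lo
    Wz <- matrix(0, nz, nzs)
    Wz[cbind(lo, seq_len(nzs))] <- 1 - fr_
    Wz[cbind(lo + 1L, seq_len(nzs))] <- fr_
    Bx <- matrix(0, nds, nd)
    Bx[cbind(seq_len(nds), rep(seq_len(nd), each = ss))] <- 1 / ss
    Bz <- matrix(0, nzs, nz)
    Bz[cbind(seq_len(nzs), rep(seq_len(nz), each = ss))] <- 1 / ss
  }

  fx <- fftfreq(nds) / (vs / ss)
  fz <- fftfreq(nzs) / (vs / ss)
  f2 <- outer(fx^2, fz^2, "+")
  H <- exp(-1i * pi * lambda * D_um * f2)
  mtf <- NULL
  if (geometry$psf_fwhm_px > 0) {
    sig <- geometry$psf_fwhm_px / (2 * sqrt(2 * log(2)))
    fpx2 <- outer(fftfreq(nd)^2, fftfreq(nz)^2, "+")
    mtf <- exp(-2 * pi^2 * sig^2 * fpx2)  # frequencies in cycles/px
  }

  frames <- array(0, dim = c(nd, nz, na))
  for (a in seq_len(na)) {
    phi <- -(2 * pi / lambda) * pd[, a, ]
    amp <- exp(-(2 * pi / lambda) * pb[, a, ])
    if (ss > 1L) { phi <- phi %*% Wz; amp <- amp %*% Wz }
    U0 <- amp * exp(1i * phi)
    I <- Mod(ifft2(fft2(U0) * H))^2
    if (ss > 1L) I <- t(Bx) %*% I %*% Bz
    if (!is.null(mtf)) I <- Re(ifft2(fft2(I) * mtf))
    frames[, , a] <- I
  }

  # smooth illumination profile and dark offset
  gx <- seq_len(nd); gz <- seq_len(nz)
  prof <- 1 + 0.2 * outer(exp(-(gx - nd / 2)^2 / (2 * (0.4 * nd)^2)),
                          exp(-(gz - nz / 2)^2 / (2 * (0.4 * nz)^2)))
  scale <- if (noise_photons > 0) noise_photons else 1
  flats <- array(0, dim = c(nd, nz, n_flat))
  darks <- array(0, dim = c(nd, nz, n_dark))
  if (noise_photons > 0) {
    with_seed(seed, {
      for (a in seq_len(na))
        frames[, , a] <- stats::rpois(nd * nz,
                                      frames[, , a] * prof * scale +
                                        dark_level)
      for (i in seq_len(n_flat))
        flats[, , i] <- stats::rpois(nd * nz, prof * scale + dark_level)
      for (i in seq_len(n_dark))
        darks[, , i] <- stats::rpois(nd * nz, dark_level)
    })
  } else {
    for (a in seq_len(na))
      frames[, , a] <- frames[, , a] * prof * scale + dark_level
    for (i in seq_len(n_flat)) flats[, , i] <- prof * scale + dark_level
    for (i in seq_len(n_dark)) darks[, , i] <- dark_level
  }

  structure(list(frames = frames, flats = flats, darks = darks,
                 angles = angles, geometry = geometry,
                 corrected = FALSE, retrieved = FALSE),
            class = "projection_set")
}

#' Flat- and dark-field correction of one frame
#'
#' Returns `(raw - dark) / (flat - dark)`. Pixels where `flat - dark <= 0`
#' are filled with the median of the valid pixels and counted in
#' attribute `"masked"`.
#'
#' @param raw,flat,dark numeric matrices of identical shape.
#' @return corrected frame.
#' @export
correct_frame <- function(raw, flat, dark) {
  if (!identical(dim(raw), dim(flat)) || !identical(dim(raw), dim(dark)))
    stop("frames must have the same shape")
  denom <- flat - dark
  bad <- denom <= 0
  if (all(bad)) stop("correction error: flat - dark <= 0 everywhere")
  out <- (raw - dark) / ifelse(bad, 1, denom)
  if (any(bad)) out[bad] <- stats::median(out[!bad])
  attr(out, "masked") <- sum(bad)
  out
}

#' Flat/dark-correct a projection set
#'
#' Averages the flat and dark stacks and applies [correct_frame()] to
#' every projection.
#'
#' @param ps a `projection_set` from [simulate_projections()].
#' @return the corrected `projection_set` (`corrected = TRUE`).
#' @export
flat_dark_correct <- function(ps) {
  stopifnot(inherits(ps, "projection_set"))
  flat <- apply(ps$flats, c(1, 2), mean)
  dark <- apply(ps$darks, c(1, 2), mean)
  masked <- 0L
  for (a in seq_len(dim(ps$frames)[3])) {
    cf <- correct_frame(ps$frames[, , a], flat, dark)
    masked <- masked + attr(cf, "masked")
    ps$frames[, , a] <- cf
  }
  ps$corrected <- TRUE
  ps$masked_pixels <- masked
  ps
}

#' Single-distance phase retrieval (phase-attenuation duality)
#'
#' For a single-material object whose delta/beta ratio is known, dividing
#' each corrected frame's Fourier transform by
#' `1 + pi * lambda * D * (delta/beta) * |f|^2` (|f| in cycles per
#' micrometre) removes the propagation fringes; `-log` of the result is
#' the attenuation projection `(4*pi/lambda) * integral(beta) dz`, a
#' thickness-like map. As `delta_beta_ratio -> 0` the filter tends to the
#' identity and the output to plain `-log(frame)`.
#'
#' @param ps corrected `projection_set`.
#' @param delta_beta_ratio the assumed delta/beta of the material (> 0).
#' @return `projection_set` of retrieved maps (`retrieved = TRUE`).
#' @export
phase_retrieve <- function(ps, delta_beta_ratio) {
  stopifnot(inherits(ps, "projection_set"))
  if (!isTRUE(ps$corrected))
    stop("state error: projections must be flat/dark corrected before ",
         "phase retrieval")
  if (delta_beta_ratio <= 0)
    stop("value error: delta_beta_ratio must be positive")
  g <- ps$geometry
  lambda <- g$wavelength_um
  D_um <- g$distance_cm * 1e4
  nd <- dim(ps$frames)[1]; nz <- dim(ps$frames)[2]
  f2 <- outer((fftfreq(nd) / g$pixel_size_um)^2,
              (fftfreq(nz) / g$pixel_size_um)^2, "+")
  filt <- 1 + pi * lambda * D_um * delta_beta_ratio * f2
  for (a in seq_len(dim(ps$frames)[3])) {
    sm <- Re(ifft2(fft2(ps$frames[, , a]) / filt))
    ps$frames[, , a] <- -log(pmax(sm, 1e-12))
  }
  ps$retrieved <- TRUE
  ps
}

# Frequency response of the band-limited ramp, built from the exact
# spatial-domain Ram-Lak kernel (avoids the DC bias of sampling |f|
# directly on the frequency grid).
ramp_filter <- function(np, filter_name) {
  h <- numeric(np)
  h[1] <- 0.25
  k <- seq(1, np / 2, by = 2)
  h[1 + k] <- -1 / (pi * k)^2
  h[np + 1 - k] <- -1 / (pi * k)^2
  H <- Re(stats::fft(h))
  if (filter_name == "shepp-logan") {
    f <- abs(fftfreq(np))
    w <- pi * f
    H <- H * ifelse(w == 0, 1, sin(w) / w)
  }
  H
}

#' Filtered back-projection reconstruction
#'
#' Slice-by-slice parallel-beam FBP of the (retrieved) projection stack:
#' each projection row is ramp-filtered in frequency space and smeared
#' back across the centred reconstruction grid. Output voxel size equals
#' the detector pixel size; for retrieved input the voxel values are the
#' linear attenuation coefficient `mu = 4*pi*beta/lambda` per micrometre.
#'
#' @param ps a `projection_set` (corrected, typically retrieved).
#' @param filter_name `"ramp"` or `"shepp-logan"`.
#' @return A [voxel_volume].
#' @export
fbp_reconstruct <- function(ps, filter_name = c("ramp", "shepp-logan")) {
  stopifnot(inherits(ps, "projection_set"))
  filter_name <- match.arg(filter_name)
  nd <- dim(ps$frames)[1]; nz <- dim(ps$frames)[2]
  na <- dim(ps$frames)[3]
  if (na < 2) stop("insufficient data: at least 2 angles required")
  if (max(abs(diff(ps$angles) - diff(ps$angles)[1])) > 1e-9)
    stop("angles must uniformly span 180 degrees")
  np <- 2^ceiling(log2(2 * nd))
  H <- ramp_filter(np, filter_name)
  # sinogram (nd, na, nz): filter every (angle, slice) projection at once
  sino <- aperm(ps$frames, c(1, 3, 2))
  m <- matrix(0, np, na * nz)
  m[seq_len(nd), ] <- sino
  M <- stats::mvfft(m) * H
  Q <- Re(stats::mvfft(M, inverse = TRUE)) / np
  sino_f <- array(Q[seq_len(nd), ], dim = c(nd, na, nz))
  vol <- array(cpp_backproject(as.double(sino_f), c(nd, na, nz),
                               ps$angles),
               dim = c(nd, nd, nz)) / ps$geometry$pixel_size_um
  voxel_volume(vol, ps$geometry$pixel_size_um)
}

#' Convert a reconstructed attenuation map to a beta map
#'
#' @param volume FBP output (`mu` per micrometre).
#' @param geometry the acquisition [beam_geometry()].
#' @return A [voxel_volume] of the attenuation index beta.
#' @export
mu_to_beta <- function(volume, geometry) {
  voxel_volume(volume$data * geometry$wavelength_um / (4 * pi),
               volume$voxel_size_um)
}

#' Build an optical phantom from a truth label grid
#'
#' @param truth `phantom_truth`.
#' @param optics per-class optical constants, see [tissue_optics()].
#' @return An [optical_phantom()] (vessels/sinusoids/channels = lumen).
#' @export
optical_from_truth <- function(truth, optics = tissue_optics()) {
  lab <- truth$labels
  delta <- array(optics$parenchyma["delta"], dim = dim(lab))
  beta <- array(optics$parenchyma["beta"], dim = dim(lab))
  lum <- lab %in% c(LBL_PORTAL, LBL_CENTRAL, LBL_SINUSOID) |
    lab >= LBL_CHANNEL0
  inf <- lab >= LBL_INFARCT0 & lab < LBL_CHANNEL0
  delta[lum] <- optics$lumen["delta"]; beta[lum] <- optics$lumen["beta"]
  delta[inf] <- optics$infarct["delta"]; beta[inf] <- optics$infarct["beta"]
  optical_phantom(delta, beta, truth$voxel_size_um)
}
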