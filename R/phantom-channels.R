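# Infarct-sinusoidal microchannels.
#
# At the submicron scale each infarct is connected to the sinusoid
# network by a number of thin tubes drawn from a zero-truncated Poisson
# law whose MEAN equals the day preset (the truncation parameter is
# solved for, so recovered sample means are directly comparable to the
# preset). Channels leave the infarct surface in well-separated
# directions and run to a nearby sinusoid. At the lobe scale (3.25 um
# voxels) the ~3.4 um channels are sub-voxel and cannot be rasterized.

# lambda of a zero-truncated Poisson with the requested mean (> 1)
ztp_lambda <- function(m) {
  if (m <= 1 + 1e-9) return(1e-8)
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 c(1e-8, 10 * m))$root
}

rztp <- function(n, lambda) {
  out <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      k <- stats::rpois(1, lambda)
      if (k > 0L) { out[i] <- k; break }
    }
  }
  out
}

# capsule rasterization restricted to parenchyma (label 0)
capsule_voxels <- function(labels, d, p, q, r) {
  lo <- pmax(floor(pmin(p, q) - r - 1), 1)
  hi <- pmin(ceiling(pmax(p, q) + r + 1), d)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  gx <- rep(xs, times = length(ys) * length(zs))
  gy <- rep(rep(ys, each = length(xs)), times = length(zs))
  gz <- rep(zs, each = length(xs) * length(ys))
  v <- q - p; vv <- sum(v^2)
  wx <- gx - p[1]; wy <- gy - p[2]; wz <- gz - p[3]
  t <- if (vv > 0) pmin(pmax((wx * v[1] + wy * v[2] + wz * v[3]) / vv, 0), 1)
       else 0
  dx <- wx - t * v[1]; dy <- wy - t * v[2]; dz <- wz - t * v[3]
  inside <- dx * dx + dy * dy + dz * dz <= r * r
  ind <- xyz_to_ind(cbind(gx[inside], gy[inside], gz[inside]), d)
  ind[labels[ind] == 0L]
}

# does the channel form one component touching both its infarct and a
# sinusoid voxel?
channel_valid <- function(labels, vox, code_u, d) {
  if (length(vox) == 0L) return(FALSE)
  m <- array(FALSE, dim = d); m[vox] <- TRUE
  bb <- bbox_of(m, pad = 1L)
  mc <- crop_bbox(m, bb)
  if (max(label_array(mc, 26L)) != 1L) return(FALSE)
  near <- crop_bbox(labels, bb)
  touch <- dilate1(mc) & !mc
  any(near[touch] == code_u) && any(near[touch] == LBL_SINUSOID)
}

#' Connect infarcts to sinusoids with microchannels
#'
#' Draws a per-infarct channel count from a zero-truncated Poisson law
#' with mean `params$microchannel_count_mean` (or `counts`, if supplied)
#' and rasterizes each channel as a tube of diameter
#' `params$microchannel_diameter_um` from the infarct surface to a nearby
#' sinusoid. Every channel is validated to be a single 26-connected
#' component touching both its infarct and a sinusoid.
#'
#' @param params a [phantom_params()] object (submicron scale).
#' @param truth `phantom_truth` with infarcts and sinusoids present.
#' @param counts optional integer vector of forced channel counts, one
#'   per infarct unit (overrides the random law).
#' @return The updated `phantom_truth` with channel labels and a filled
#'   `channel_table`.
#' @export
place_microchannels <- function(params, truth, counts = NULL) {
  if (params$scale == "lobe")
    stop("scale error: microchannels (~",
         params$microchannel_diameter_um,
         " um) are sub-voxel at the lobe scale (3.25 um) and can only be ",
         "generated on submicron phantoms")
  d <- dims3(truth$labels)
  it <- truth$infarct_table
  if (is.null(it) || nrow(it) == 0L) return(truth)
  if (is.null(counts) && params$microchannel_count_mean == 0) return(truth)
  sin_idx <- which(truth$labels == LBL_SINUSOID)
  if (length(sin_idx) == 0L)
    stop("no sinusoid voxels present; sinusoids are required for ",
         "microchannel placement")
  S <- ind_to_xyz(sin_idx, d)
  labels <- truth$labels
  r_ch <- params$microchannel_diameter_um / params$voxel_size_um / 2

  with_seed(stage_seed(params$seed, 303L), {
    if (is.null(counts)) {
      lam <- ztp_lambda(params$microchannel_count_mean)
      counts <- rztp(nrow(it), lam)
      # larger lesions carry more conduits: rank-match the drawn counts
      # to lesion size (a small lesion cannot host many spatially
      # distinct channels); the marginal count law is unchanged
      counts <- sort(counts)[rank(it$r_vox, ties.method = "first")]
    }
    stopifnot(length(counts) == nrow(it))
    ch_rows <- list()
    chan_id <- nrow(truth$channel_table)
    for (u in seq_len(nrow(it))) {
      code_u <- LBL_INFARCT0 + it$infarct_id[u]
      c0 <- c(it$cx[u], it$cy[u], it$cz[u])
      # spherical Fibonacci directions under a random rotation: channels
      # leave the infarct as evenly spread as possible, so their surface
      # contact patches stay distinct and countable
      m <- counts[u]
      i <- seq_len(m)
      zf <- 1 - 2 * (i - 0.5) / m
      phi <- i * 2.39996322972865
      fib <- cbind(cos(phi) * sqrt(1 - zf^2), sin(phi) * sqrt(1 - zf^2),
                   zf)
      rot <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
      fib <- fib %*% rot
      placed_u <- 0L
      for (ch in seq_len(counts[u])) {
        done <- FALSE
        for (try in seq_len(40L)) {
          dir <- if (try == 1L) fib[ch, ] else {
            cand <- stats::rnorm(3); cand / sqrt(sum(cand^2))
          }
          # march to the infarct surface
          tt <- 0; p_exit <- NULL
          repeat {
            tt <- tt + 0.5
            pos <- c0 + dir * tt
            rp <- round(pos)
            if (any(rp < 1) || any(rp > d)) break
            if (labels[matrix(rp, 1)] != code_u) { p_exit <- pos; break }
          }
          if (is.null(p_exit)) next
          p_start <- c0 + dir * max(tt - 2, 0.5)
          # pick a sinusoid target near the exit, preferring the exit
          # direction
          dv <- S - matrix(p_exit, nrow(S), 3, byrow = TRUE)
          dist <- sqrt(rowSums(dv^2))
          cosang <- (dv %*% dir) / pmax(dist, 1e-9)
          elig <- dist >= 3 & dist <= 45
          if (!any(elig)) elig <- dist >= 3
          if (!any(elig)) next
          score <- dist * (2 - cosang)
          score[!elig] <- Inf
          tgt <- as.numeric(S[which.min(score), ])
          vox <- capsule_voxels(labels, d, p_start, tgt, r_ch)
          labels[vox] <- LBL_CHANNEL0 + chan_id + 1L
          if (channel_valid(labels, vox, code_u, d)) {
            chan_id <- chan_id + 1L
            placed_u <- placed_u + 1L
            ch_rows[[length(ch_rows) + 1L]] <- data.frame(
              channel_id = chan_id, infarct_id = it$infarct_id[u],
              diameter_um = params$microchannel_diameter_um,
              n_voxels = length(vox))
            done <- TRUE
          } else {
            labels[vox] <- 0L
          }
          if (done) break
        }
      }
      it$n_channels[u] <- placed_u
      it$channel_diam_um[u] <- if (placed_u > 0)
        params$microchannel_diameter_um else NA_real_
    }
    truth$labels <- labels
    truth$infarct_table <- it
    truth$channel_table <- rbind(truth$channel_table,
                                 do.call(rbind, ch_rows))
    truth
  })
}
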