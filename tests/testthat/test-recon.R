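# independent R-side ray integrator (bilinear sampling, same geometry
# convention) used as the line-integral oracle
oracle_project <- function(slice, angle, step = 0.5) {
  n <- nrow(slice)
  c0 <- (n - 1) / 2
  L <- sqrt(2) * n
  svals <- seq(-L / 2, L / 2, by = step)
  ct <- cos(angle); st <- sin(angle)
  out <- numeric(n)
  for (t in seq_len(n)) {
    tv <- t - 1 - c0
    x <- c0 + tv * ct - svals * st + 1
    y <- c0 + tv * st + svals * ct + 1
    ok <- x >= 1 & y >= 1 & x < n & y < n
    x <- x[ok]; y <- y[ok]
    ix <- floor(x); iy <- floor(y)
    fx <- x - ix; fy <- y - iy
    v <- slice[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
      slice[cbind(ix + 1, iy)] * fx * (1 - fy) +
      slice[cbind(ix, iy + 1)] * (1 - fx) * fy +
      slice[cbind(ix + 1, iy + 1)] * fx * fy
    out[t] <- sum(v) * step
  }
  out
}

test_that("geometry derives the wavelength and carries the presets", {
  g <- beam_geometry(16, 28, 3.25, 1200)
  expect_equal(g$wavelength_um, 1.23984193e-4 / 16)
  lobe <- geometry_preset("lobe")
  expect_equal(c(lobe$energy_keV, lobe$distance_cm, lobe$pixel_size_um,
                 lobe$n_angles), c(16, 28, 3.25, 1200))
  sub <- geometry_preset("submicron")
  expect_equal(c(sub$energy_keV, sub$distance_cm, sub$pixel_size_um,
                 sub$n_angles), c(14, 16, 0.65, 900))
  expect_error(beam_geometry(16, -1, 3.25, 100), "geometry error")
})

test_that("flat/dark correction is exact pixel arithmetic", {
  f <- matrix(250, 8, 8); d <- matrix(50, 8, 8); r <- matrix(150, 8, 8)
  expect_true(all(correct_frame(r, f, d) == 0.5))
  expect_true(all(correct_frame(f, f, d) == 1))
  set.seed(2)
  rr <- matrix(runif(64, 100, 200), 8)
  ff <- matrix(runif(64, 220, 260), 8)
  dd <- matrix(runif(64, 40, 60), 8)
  expect_equal(unclass(correct_frame(rr, ff, dd)), (rr - dd) / (ff - dd),
               ignore_attr = TRUE)
  expect_error(correct_frame(rr, dd, dd), "correction error")
  # masked pixels are filled and counted
  ff2 <- ff; ff2[1, 1] <- 0
  cf <- correct_frame(rr, ff2, dd)
  expect_equal(attr(cf, "masked"), 1L)
  expect_true(is.finite(cf[1, 1]))
})

test_that("an empty phantom corrects to unit transmission", {
  n <- 24
  ph <- optical_phantom(array(0, dim = rep(n, 3)),
                        array(0, dim = rep(n, 3)), 3.25)
  ps <- simulate_projections(ph, beam_geometry(16, 28, 3.25, 4), 0)
  ps <- flat_dark_correct(ps)
  expect_lt(max(abs(ps$frames - 1)), 1e-9)
})

test_that("pure absorption at vanishing distance is Beer-Lambert", {
  n <- 24
  beta <- array(0, dim = rep(n, 3))
  x <- 1:n
  disk <- outer((x - 12.5)^2, (x - 12.5)^2, "+") <= 36
  for (k in 1:n) beta[, , k][disk] <- 5e-10
  ph <- optical_phantom(array(0, dim = rep(n, 3)), beta, 3.25)
  g <- beam_geometry(16, 1e-9, 3.25, 3, psf_fwhm_px = 0)
  ps <- flat_dark_correct(simulate_projections(ph, g, 0, supersample = 1))
  for (a in 1:3) {
    pbeta <- oracle_project(beta[, , 12], ps$angles[a]) * 3.25
    expected <- exp(-(4 * pi / g$wavelength_um) * pbeta)
    expect_lt(max(abs(ps$frames[, 12, a] - expected)), 1e-6)
  }
})

test_that("a pure-phase rod casts visible propagation fringes", {
  n <- 32
  delta <- array(0, dim = rep(n, 3))
  delta[14:18, 14:18, ] <- 2e-7
  ph <- optical_phantom(delta, array(0, dim = rep(n, 3)), 3.25)
  g <- beam_geometry(16, 28, 3.25, 2, psf_fwhm_px = 0)
  ps <- flat_dark_correct(simulate_projections(ph, g, 0))
  # absorption is zero, so all structure in the frame is phase contrast
  expect_gt(var(as.vector(ps$frames[, , 1])), 1e-8)
})

test_that("phase retrieval inverts to thickness maps", {
  # flat unit frames retrieve to zero
  g <- beam_geometry(16, 28, 3.25, 2)
  ps <- structure(list(frames = array(1, dim = c(16, 16, 2)),
                       angles = c(0, pi / 2), geometry = g,
                       corrected = TRUE), class = "projection_set")
  out <- phase_retrieve(ps, 1000)
  expect_lt(max(abs(out$frames)), 1e-9)
  # ratio -> 0: the filter collapses to -log(frame)
  set.seed(4)
  fr <- array(runif(16 * 16 * 2, 0.5, 1), dim = c(16, 16, 2))
  ps$frames <- fr
  out2 <- phase_retrieve(ps, 1e-12)
  expect_equal(out2$frames, -log(fr), tolerance = 1e-6)
  # guards
  expect_error(phase_retrieve(ps, -1), "value error")
  ps$corrected <- FALSE
  expect_error(phase_retrieve(ps, 1000), "state error")
})

test_that("retrieved maps match the attenuation projections to 2% RMS", {
  n <- 48
  opt <- tissue_optics()
  ball <- make_sphere(15, n)
  delta <- array(0, dim = rep(n, 3)); beta <- array(0, dim = rep(n, 3))
  delta[ball] <- opt$parenchyma["delta"]
  beta[ball] <- opt$parenchyma["beta"]
  g <- beam_geometry(16, 28, 3.25, 4, psf_fwhm_px = 0)
  ps <- flat_dark_correct(simulate_projections(
    optical_phantom(delta, beta, 3.25), g, 0))
  ret <- phase_retrieve(ps, 1000)
  truth <- (4 * pi / g$wavelength_um) *
    oracle_project(beta[, , 24], ret$angles[1]) * 3.25
  got <- ret$frames[, 24, 1]
  interior <- which(truth > 0.5 * max(truth))
  rms <- sqrt(mean((got[interior] - truth[interior])^2)) / max(truth)
  expect_lt(rms, 0.02)
})

test_that("the retrieval filter is a low-pass, stronger at higher ratio", {
  set.seed(5)
  g <- beam_geometry(16, 28, 3.25, 1)
  fr <- array(runif(32 * 32, 0.8, 1.2), dim = c(32, 32, 1))
  hf_power <- function(x) {
    f <- Mod(stats::fft(x))^2
    sum(f[9:24, 9:24])  # high-frequency block
  }
  base <- hf_power(fr[, , 1])
  powers <- sapply(c(10, 100, 1000), function(ratio) {
    ps <- structure(list(frames = fr, angles = 0, geometry = g,
                         corrected = TRUE), class = "projection_set")
    out <- phase_retrieve(ps, ratio)
    hf_power(exp(-out$frames[, , 1]))  # undo the log for comparison
  })
  expect_true(all(powers <= base))
  expect_true(all(diff(powers) < 0))
})

test_that("FBP reconstructs an analytic disk quantitatively", {
  n <- 128; na <- 400; R <- 40; mu <- 0.01
  angles <- seq(0, pi, length.out = na + 1)[1:na]
  tt <- (0:(n - 1)) - (n - 1) / 2
  chord <- ifelse(abs(tt) < R, 2 * sqrt(pmax(R^2 - tt^2, 0)), 0)
  sino <- array(chord * mu, dim = c(n, 1, na))
  ps <- structure(list(frames = sino, angles = angles,
                       geometry = beam_geometry(16, 28, 1, na),
                       corrected = TRUE, retrieved = TRUE),
                  class = "projection_set")
  vol <- fbp_reconstruct(ps)
  xs <- matrix(rep(tt, n), n)
  rr <- sqrt(xs^2 + t(xs)^2)
  interior <- rr < R - 3
  err <- vol$data[, , 1][interior] - mu
  expect_lt(sqrt(mean(err^2)) / mu, 0.02)
  # zero sinogram reconstructs to zero
  ps$frames <- array(0, dim = c(n, 1, na))
  expect_true(all(fbp_reconstruct(ps)$data == 0))
  # a single angle is insufficient
  ps1 <- ps; ps1$frames <- sino[, , 1, drop = FALSE]; ps1$angles <- 0
  expect_error(fbp_reconstruct(ps1), "insufficient")
})

test_that("an impulse backprojects to its true location", {
  n <- 64; na <- 180
  angles <- seq(0, pi, length.out = na + 1)[1:na]
  c0 <- (n - 1) / 2
  x0 <- 10; y0 <- -7
  sino <- array(0, dim = c(n, 1, na))
  for (a in seq_len(na)) {
    t <- x0 * cos(angles[a]) + y0 * sin(angles[a]) + c0
    it <- floor(t); f <- t - it
    sino[it + 1, 1, a] <- 1 - f
    sino[it + 2, 1, a] <- f
  }
  ps <- structure(list(frames = sino, angles = angles,
                       geometry = beam_geometry(16, 28, 1, na),
                       corrected = TRUE, retrieved = TRUE),
                  class = "projection_set")
  vol <- fbp_reconstruct(ps)
  w <- which(vol$data[, , 1] == max(vol$data[, , 1]), arr.ind = TRUE)
  expect_lt(abs(w[1] - (x0 + c0 + 1)), 1.5)
  expect_lt(abs(w[2] - (y0 + c0 + 1)), 1.5)
})

test_that("correction and FBP are linear in their inputs", {
  set.seed(6)
  n <- 32; na <- 24
  angles <- seq(0, pi, length.out = na + 1)[1:na]
  mk <- function() array(runif(n * 1 * na), dim = c(n, 1, na))
  s1 <- mk(); s2 <- mk()
  ps <- function(fr) structure(
    list(frames = fr, angles = angles,
         geometry = beam_geometry(16, 28, 1, na), corrected = TRUE),
    class = "projection_set")
  v1 <- fbp_reconstruct(ps(s1))$data
  v2 <- fbp_reconstruct(ps(s2))$data
  v12 <- fbp_reconstruct(ps(2 * s1 - 0.5 * s2))$data
  expect_equal(v12, 2 * v1 - 0.5 * v2, tolerance = 1e-10)
})

test_that("shepp-logan filtering damps noise relative to the ramp", {
  set.seed(8)
  n <- 64; na <- 90
  angles <- seq(0, pi, length.out = na + 1)[1:na]
  fr <- array(rnorm(n * na, 0, 1), dim = c(n, 1, na))
  ps <- structure(list(frames = fr, angles = angles,
                       geometry = beam_geometry(16, 28, 1, na),
                       corrected = TRUE), class = "projection_set")
  vr <- fbp_reconstruct(ps, "ramp")$data
  vs <- fbp_reconstruct(ps, "shepp-logan")$data
  expect_lt(sd(vs), sd(vr))
})
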