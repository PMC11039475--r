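test_that("a 1D slab splits into three contiguous equal bands III, II, I", {
  d <- c(302L, 3L, 3L)
  central <- array(FALSE, d); central[1, , ] <- TRUE
  portal <- array(FALSE, d); portal[302, , ] <- TRUE
  parenchyma <- array(TRUE, d); parenchyma[c(1, 302), , ] <- FALSE
  zm <- equal_volume_zonation(parenchyma, central, portal, 1)
  # 300 parenchyma planes -> 100 per zone, ordered III, II, I
  expect_true(all(zm$zones[2:101, , ] == 3L))
  expect_true(all(zm$zones[102:201, , ] == 2L))
  expect_true(all(zm$zones[202:301, , ] == 1L))
  expect_equal(unname(zm$achieved_fractions), rep(1 / 3, 3),
               tolerance = 1e-9)
})

test_that("a ball with a point central vein gives the analytic shell radii", {
  n <- 81L; R <- 36
  parenchyma <- make_sphere(R, n)
  central <- array(FALSE, dim = rep(n, 3))
  central[(n + 1) / 2, (n + 1) / 2, (n + 1) / 2] <- TRUE
  parenchyma <- parenchyma & !central
  portal <- array(FALSE, dim = rep(n, 3)); portal[1, 1, 1] <- TRUE
  zm <- equal_volume_zonation(parenchyma, central, portal, 1)
  expect_lt(abs(zm$r3_um - R / 3^(1 / 3)), 1)
  expect_lt(abs(zm$r2_um - R * (2 / 3)^(1 / 3)), 1)
  expect_true(all(abs(zm$achieved_fractions - 1 / 3) < 0.005))
})

test_that("zones partition the grid and nest by distance", {
  p <- phantom_params(day = "1", scale = "lobe", grid_shape = 48, seed = 5)
  tr <- build_vessel_trees(p)
  parenchyma <- tr$labels == 0L
  central <- tr$labels == 2L
  zm <- equal_volume_zonation(parenchyma, central, tr$labels == 1L, 3.25)
  # partition: zones 1..3 exactly on parenchyma, 0 elsewhere
  expect_true(all(zm$zones[parenchyma] %in% 1:3))
  expect_true(all(zm$zones[!parenchyma] == 0L))
  expect_true(all(abs(zm$achieved_fractions - 1 / 3) < 0.005))
  expect_true(zm$r3_um > 0 && zm$r3_um < zm$r2_um)
  # nesting: each zone lives strictly within its distance shell
  dist_um <- infarct3d:::edt(central) * 3.25
  expect_true(all(dist_um[zm$zones == 3L] <= zm$r3_um + 1e-9))
  expect_true(all(dist_um[zm$zones == 2L] >= zm$r3_um - 1e-9))
  expect_true(all(dist_um[zm$zones == 2L] <= zm$r2_um + 1e-9))
  expect_true(all(dist_um[zm$zones == 1L] >= zm$r2_um - 1e-9))
})

test_that("thresholded distance field equals ball dilation of the veins", {
  # the equal-volume shells are level sets of the distance transform:
  # {d <= k} must equal the central mask dilated by a radius-k ball
  set.seed(3)
  d <- c(24L, 24L, 24L)
  central <- array(runif(prod(d)) < 0.01, d)
  central[12, 12, 12] <- TRUE
  dist_vox <- sqrt(brute_edt_sq(central))
  for (k in c(2, 4.5, 7)) {
    expect_identical(infarct3d:::edt(central) <= k, dist_vox <= k)
  }
})

test_that("doubling the voxel size doubles the radii, not the labels", {
  p <- phantom_params(day = "1", scale = "lobe", grid_shape = 32, seed = 2)
  tr <- build_vessel_trees(p)
  args <- list(tr$labels == 0L, tr$labels == 2L, tr$labels == 1L)
  z1 <- do.call(equal_volume_zonation, c(args, voxel_size_um = 1))
  z2 <- do.call(equal_volume_zonation, c(args, voxel_size_um = 2))
  expect_identical(z1$zones, z2$zones)
  expect_equal(z2$r3_um, 2 * z1$r3_um)
  expect_equal(z2$r2_um, 2 * z1$r2_um)
})

test_that("geodesic distance agrees with Euclidean on a convex slab", {
  d <- c(40L, 9L, 9L)
  central <- array(FALSE, d); central[1, , ] <- TRUE
  portal <- array(FALSE, d); portal[40, , ] <- TRUE
  parenchyma <- array(TRUE, d)
  parenchyma[c(1, 40), , ] <- FALSE
  zg <- equal_volume_zonation(parenchyma, central, portal, 1,
                              geodesic = TRUE)
  ze <- equal_volume_zonation(parenchyma, central, portal, 1)
  expect_identical(zg$zones, ze$zones)  # convex slab: must agree
})

test_that("infarct zone labels follow the largest-proportion rule", {
  d <- c(12L, 12L, 12L)
  zones <- array(0L, d)
  zones[1:4, , ] <- 3L; zones[5:8, , ] <- 2L; zones[9:12, , ] <- 1L
  zm <- structure(list(zones = zones, r3_um = 4, r2_um = 8,
                       achieved_fractions = rep(1 / 3, 3),
                       voxel_size_um = 1), class = "zone_map")
  inf <- array(0L, d)
  inf[3:7, 1:2, 1] <- 1L       # 40% zone III, 60% zone II -> II
  inf[9:11, 5, 5] <- 2L        # wholly zone I
  inf[c(4, 5), 9, 9] <- 3L     # exact 50/50 tie II vs III -> lower index II
  za <- assign_infarct_zones(inf, zm)
  expect_equal(za$zone, c(2L, 1L, 2L))
  expect_equal(za$p_zone2[1], 0.6)
  # unassignable component wholly in excluded voxels
  zones0 <- zones; zones0[] <- 0L
  zm0 <- zm; zm0$zones <- zones0
  za0 <- assign_infarct_zones(inf, zm0)
  expect_true(all(is.na(za0$zone)))
})

test_that("zonation rejects inconsistent inputs", {
  d <- rep(8L, 3)
  a <- array(TRUE, d); b <- array(FALSE, d)
  expect_error(equal_volume_zonation(a, b, b, 1), "empty central")
  b2 <- b; b2[1, 1, 1] <- TRUE
  expect_error(equal_volume_zonation(a, b2, b, 1), "disjoint|empty portal")
})
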