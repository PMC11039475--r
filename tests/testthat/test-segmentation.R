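test_that("a noiseless render thresholds to exactly the truth infarcts", {
  p <- phantom_params(day = "1", scale = "lobe", grid_shape = 48, seed = 3,
                      noise_sd = 0)
  ph <- generate_phantom(p)
  vessel_mask <- ph$truth$labels %in% 1:3
  mask <- segment_infarcts_threshold(ph$volume, segmentation_config(),
                                     vessel_mask = vessel_mask)
  expect_identical(unclass(mask), ph$truth$labels >= 10L,
                   ignore_attr = TRUE)
})

test_that("an all-bright volume yields an empty mask", {
  v <- voxel_volume(array(120, dim = rep(8, 3)), 3.25)
  cfg <- segmentation_config(infarct_threshold = 100)
  expect_false(any(segment_infarcts_threshold(v, cfg)))
  # degenerate histogram in auto mode warns and returns empty
  expect_warning(m <- segment_infarcts_threshold(v, segmentation_config()),
                 "degenerate")
  expect_false(any(m))
})

test_that("auto threshold survives heavy class imbalance", {
  # 0.5% dark voxels must still be split from the bright mode
  set.seed(9)
  n <- 40^3
  v <- rnorm(n, 120, 5)
  pick <- sample(n, round(0.005 * n))
  v[pick] <- rnorm(length(pick), 75, 5)
  vol <- voxel_volume(array(v, dim = rep(40, 3)), 3.25)
  mask <- segment_infarcts_threshold(vol, segmentation_config())
  thr <- attr(mask, "threshold")
  expect_gt(thr, 85)
  expect_lt(thr, 110)
})

test_that("noisy renders segment with high Dice against truth", {
  # noise_sd at 10% of the infarct-parenchyma gap
  p <- phantom_params(day = "3", scale = "lobe", grid_shape = 64, seed = 5,
                      noise_sd = 4.5)
  ph <- generate_phantom(p)
  vessel_mask <- ph$truth$labels %in% 1:3
  mask <- segment_infarcts_threshold(ph$volume, segmentation_config(),
                                     vessel_mask = vessel_mask)
  truth <- ph$truth$labels >= 10L
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gt(dice, 0.95)
})

test_that("re-thresholding a binary image is idempotent", {
  set.seed(1)
  m <- array(runif(16^3) < 0.2, dim = rep(16, 3))
  v <- voxel_volume(array(as.double(!m), dim = dim(m)), 1)  # lesions dark
  cfg <- segmentation_config(infarct_threshold = 0.5)
  out <- segment_infarcts_threshold(v, cfg)
  expect_identical(unclass(out), m, ignore_attr = TRUE)
  again <- segment_infarcts_threshold(
    voxel_volume(array(as.double(!out), dim = dim(m)), 1), cfg)
  expect_identical(unclass(again), unclass(out), ignore_attr = TRUE)
})

test_that("region growing captures a uniform tube exactly", {
  d <- c(32L, 16L, 16L)
  v <- array(100, dim = d)
  v[8:24, 6:10, 6:10] <- 20
  vol <- voxel_volume(v, 1)
  cfg <- segmentation_config(vessel_seeds = cbind(16L, 8L, 8L, 1L),
                             grow_tolerance = 10)
  lab <- segment_vessels_region_growing(vol, cfg)
  expect_identical(unclass(lab) == 1L, v == 20, ignore_attr = TRUE)
  expect_equal(attr(lab, "conflicts"), 0L)
})

test_that("zero tolerance grows only the connected equal-value plateau", {
  d <- c(12L, 12L, 12L)
  v <- array(50, dim = d)
  v[3:5, 3:5, 3:5] <- 10
  v[9:11, 9:11, 9:11] <- 10  # same value, not connected to the seed
  vol <- voxel_volume(v, 1)
  cfg <- segmentation_config(vessel_seeds = cbind(4L, 4L, 4L, 1L),
                             grow_tolerance = 0)
  lab <- segment_vessels_region_growing(vol, cfg)
  expect_equal(sum(lab == 1L), 27L)
  expect_true(all(which(lab == 1L) %in%
                    which(array(seq_len(prod(d)), d) > 0 & v == 10)))
})

test_that("region growth is monotone in the tolerance", {
  # on data with well-separated intensity classes, a larger tolerance
  # can only enlarge the grown region (the running-mean rule is
  # order-dependent in general, see the methods vignette)
  set.seed(12)
  v <- array(100, dim = rep(20, 3))
  v[5:15, 5:15, 5:15] <- 40 + rnorm(11^3, 0, 2)
  vol <- voxel_volume(v, 1)
  prev <- NULL
  for (tol in c(10, 20, 80)) {
    cfg <- segmentation_config(vessel_seeds = cbind(10L, 10L, 10L, 1L),
                               grow_tolerance = tol)
    cur <- segment_vessels_region_growing(vol, cfg) == 1L
    if (!is.null(prev)) expect_true(all(cur[prev]))
    prev <- cur
  }
  expect_true(all(prev))  # tolerance above the class gap floods all
})

test_that("both phantom trees region-grow to near-perfect Dice", {
  p <- phantom_params(day = "1", scale = "lobe", grid_shape = 64, seed = 6,
                      noise_sd = 0)
  ph <- generate_phantom(p)
  seeds <- vessel_seed_points(ph$truth)
  cfg <- segmentation_config(vessel_seeds = seeds, grow_tolerance = 15)
  lab <- segment_vessels_region_growing(ph$volume, cfg)
  for (lbl in 1:2) {
    tm <- ph$truth$labels == lbl
    gm <- lab == lbl
    dice <- 2 * sum(tm & gm) / (sum(tm) + sum(gm))
    expect_gt(dice, 0.98)
  }
})

test_that("seeds outside the volume are a coordinate error", {
  v <- voxel_volume(array(0, dim = rep(8, 3)), 1)
  cfg <- segmentation_config(vessel_seeds = cbind(9L, 1L, 1L, 1L))
  expect_error(segment_vessels_region_growing(v, cfg), "outside")
})

test_that("connectivity semantics match the digital-topology definitions", {
  d <- rep(6L, 3)
  m <- array(FALSE, d)
  m[2, 2, 2] <- TRUE; m[3, 3, 3] <- TRUE  # touch only diagonally
  l26 <- label_components(m, 1, segmentation_config(min_component_um3 = 0))
  l6 <- label_components(m, 1, segmentation_config(connectivity = 6L,
                                                   min_component_um3 = 0))
  expect_equal(nrow(l26$table), 1L)
  expect_equal(nrow(l6$table), 2L)
})

test_that("a single voxel at 3.25 um measures 34.328 um^3", {
  m <- array(FALSE, dim = rep(6, 3)); m[3, 3, 3] <- TRUE
  lc <- label_components(m, 3.25, segmentation_config(min_component_um3 = 0))
  expect_equal(lc$table$volume_um3, 3.25^3, tolerance = 1e-9)
  expect_equal(round(lc$table$volume_um3, 3), 34.328)
})

test_that("labels are sorted by size and filtered by physical volume", {
  d <- rep(20L, 3)
  m <- array(FALSE, d)
  m[2:4, 2:4, 2:4] <- TRUE       # 27 voxels
  m[10:15, 10:15, 10:15] <- TRUE # 216 voxels
  m[18, 18, 18] <- TRUE          # 1 voxel
  lc <- label_components(m, 1, segmentation_config(min_component_um3 = 2))
  expect_equal(lc$table$n_voxels, c(216L, 27L))
  expect_equal(max(lc$labels), 2L)
  # empty mask is not an error
  l0 <- label_components(array(FALSE, d), 1, segmentation_config())
  expect_equal(nrow(l0$table), 0L)
})

test_that("component labelling agrees with brute-force flood fill", {
  set.seed(21)
  for (conn in c(6L, 18L, 26L)) {
    m <- array(runif(14^3) < 0.25, dim = rep(14, 3))
    fast <- infarct3d:::label_array(m, conn)
    slow <- brute_label(m, conn)
    # same partition: label images must be relabellings of each other
    expect_equal(max(fast), max(slow))
    key <- paste(fast[m], slow[m])
    expect_equal(length(unique(key)), max(fast))
  }
})

test_that("phantom truth with k units renders to k components", {
  p <- phantom_params(day = "1", scale = "lobe", grid_shape = 64, seed = 2,
                      noise_sd = 0)
  ph <- generate_phantom(p)
  mask <- segment_infarcts_threshold(
    ph$volume, segmentation_config(),
    vessel_mask = ph$truth$labels %in% 1:3)
  lc <- label_components(mask, 3.25, segmentation_config())
  expect_equal(nrow(lc$table), nrow(ph$truth$infarct_table))
})
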