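test_that("identical parameters give bit-identical phantoms", {
  p <- phantom_params(day = "3", scale = "lobe", grid_shape = 48, seed = 7)
  a <- generate_phantom(p)
  b <- generate_phantom(phantom_params(day = "3", scale = "lobe",
                                       grid_shape = 48, seed = 7))
  expect_identical(a$truth$labels, b$truth$labels)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$infarct_table, b$truth$infarct_table)
})

test_that("portal and central trees are disjoint and never adjacent", {
  for (seed in c(7, 19)) {
    p <- phantom_params(day = "7", scale = "lobe", grid_shape = 64,
                        seed = seed)
    tr <- build_vessel_trees(p)
    portal <- tr$labels == 1L
    central <- tr$labels == 2L
    expect_false(any(portal & central))
    expect_false(any(infarct3d:::dilate1(portal) & central))
  }
})

test_that("truth label classes are pairwise disjoint by construction", {
  ph <- generate_phantom(phantom_params(day = "1", scale = "submicron",
                                        grid_shape = 48, seed = 3),
                         render = FALSE)
  lab <- ph$truth$labels
  # each voxel carries exactly one code, so the classes cannot overlap;
  # assert the code blocks are the expected ones
  expect_true(all(lab %in% c(0:3,
                             10L + ph$truth$infarct_table$infarct_id,
                             1000L + ph$truth$channel_table$channel_id)))
})

test_that("grid too small to hold the trees raises a placement error", {
  expect_error(build_vessel_trees(
    phantom_params(day = "1", scale = "lobe", grid_shape = 16, seed = 1)),
    "portal")
})

test_that("day presets are monotone in severity", {
  for (scale in c("lobe", "submicron")) {
    pre <- phantom_presets(scale)
    expect_true(all(diff(pre$n_infarcts_ref) >= 0))
    expect_true(all(diff(pre$confluent_fraction) >= 0))
    expect_true(all(diff(pre$microchannel_count_mean) >= 0))
    expect_true(all(diff(pre$sphericity_roughness) >= 0))
  }
  # expected total-volume multiplier day7/day1: counts x mean r^3 x
  # cluster-overlap and roughness inflation, calibrated to 9
  pre <- phantom_presets("lobe")
  er3 <- (pre$r_max_um^4 - pre$r_min_um^4) /
    (4 * (pre$r_max_um - pre$r_min_um))
  infl <- (1 + pre$confluent_fraction * 0.847) *
    (1 + 3 * pre$sphericity_roughness^2 * 0.88)
  mult <- (pre$n_infarcts_ref * er3 * infl)
  expect_lt(abs(mult[5] / mult[2] - 9), 0.1)
})

test_that("zero confluent fraction yields only single-blob units", {
  p <- phantom_params(day = "7", scale = "lobe", grid_shape = 64, seed = 2,
                      confluent_fraction = 0)
  ph <- generate_phantom(p, render = FALSE)
  expect_true(all(ph$truth$infarct_table$n_blobs == 1L))
  expect_equal(anyDuplicated(ph$truth$infarct_table$cluster_id), 0L)
})

test_that("day-1 truth places most infarcts in zone I", {
  zones <- unlist(lapply(1:3, function(s) {
    ph <- generate_phantom(phantom_params(day = "1", scale = "lobe",
                                          grid_shape = 96, seed = s),
                           render = FALSE)
    ph$truth$infarct_table$origin_zone
  }))
  expect_gt(mean(zones == 1L), 0.5)
})

test_that("infarcts never invade vein lumina and units never touch", {
  p <- phantom_params(day = "7", scale = "lobe", grid_shape = 64, seed = 4)
  veins <- build_vessel_trees(p)$labels
  ph <- generate_phantom(p, render = FALSE)
  lab <- ph$truth$labels
  # every vein voxel is untouched by infarct placement
  expect_identical(lab[veins %in% 1:2], veins[veins %in% 1:2])
  # pairwise non-adjacency of infarct units
  ids <- ph$truth$infarct_table$infarct_id
  for (u in ids) {
    m <- lab == 10L + u
    halo <- infarct3d:::dilate1(m) & !m
    expect_false(any(lab[halo] >= 10L & lab[halo] < 1000L))
  }
})

test_that("an impossible request trips the occupancy capacity error", {
  expect_error(generate_phantom(
    phantom_params(day = "7", scale = "lobe", grid_shape = 32, seed = 1,
                   n_infarcts = 400L), render = FALSE),
    "capacity")
})

test_that("microchannels connect their infarct to a sinusoid", {
  ph <- generate_phantom(phantom_params(day = "3", scale = "submicron",
                                        grid_shape = 48, seed = 6),
                         render = FALSE)
  lab <- ph$truth$labels
  ct <- ph$truth$channel_table
  expect_gt(nrow(ct), 0)
  for (r in seq_len(nrow(ct))) {
    chan <- lab == 1000L + ct$channel_id[r]
    expect_true(any(chan))
    infm <- lab == 10L + ct$infarct_id[r]
    sinm <- lab == 3L
    expect_true(brute_path_exists(chan, infm, sinm))
  }
  # per-unit counts in the truth table match the labels
  tab <- table(factor(ct$infarct_id,
                      levels = ph$truth$infarct_table$infarct_id))
  expect_equal(as.integer(tab), ph$truth$infarct_table$n_channels)
})

test_that("forced channel counts are honoured exactly", {
  p <- phantom_params(day = "1", scale = "submicron", grid_shape = 48,
                      seed = 9, n_infarcts = 1L)
  tr <- build_vessel_trees(p)
  zones <- equal_volume_zonation(tr$labels == 0L, tr$labels == 2L,
                                 tr$labels == 1L, p$voxel_size_um)
  tr <- place_infarcts(p, tr, zones)
  tr <- place_microchannels(p, tr, counts = 3L)
  expect_equal(tr$infarct_table$n_channels, 3L)
  expect_equal(nrow(tr$channel_table), 3L)
})

test_that("channel placement is refused at the lobe scale", {
  p <- phantom_params(day = "7", scale = "lobe", grid_shape = 48, seed = 1)
  tr <- build_vessel_trees(p)
  expect_error(place_microchannels(p, tr), "scale error")
})

test_that("zero channel mean places no channels", {
  p <- phantom_params(day = "1", scale = "submicron", grid_shape = 48,
                      seed = 2, microchannel_count_mean = 0)
  ph <- generate_phantom(p, render = FALSE)
  expect_equal(nrow(ph$truth$channel_table), 0L)
  expect_false(any(ph$truth$labels >= 1000L))
})

test_that("zero-truncated Poisson draws have the requested mean", {
  lam <- infarct3d:::ztp_lambda(5.47)
  expect_equal(lam / (1 - exp(-lam)), 5.47, tolerance = 1e-6)
  set.seed(1)
  x <- infarct3d:::rztp(4000, lam)
  expect_true(all(x >= 1L))
  expect_lt(abs(mean(x) - 5.47), 3 * sd(x) / sqrt(4000))
})

test_that("noiseless rendering is exactly piecewise constant", {
  p <- phantom_params(day = "1", scale = "lobe", grid_shape = 48, seed = 8,
                      noise_sd = 0)
  ph <- generate_phantom(p)
  v <- ph$volume$data
  lab <- ph$truth$labels
  gl <- p$gray_levels
  expect_true(all(v[lab == 0L] == gl[["parenchyma"]]))
  expect_true(all(v[lab == 1L] == gl[["portal"]]))
  expect_true(all(v[lab >= 10L] == gl[["infarct"]]))
})

test_that("infarcts render darker than parenchyma beyond the noise", {
  p <- phantom_params(day = "3", scale = "lobe", grid_shape = 64, seed = 2)
  ph <- generate_phantom(p)
  v <- ph$volume$data
  lab <- ph$truth$labels
  expect_lt(mean(v[lab >= 10L]),
            mean(v[lab == 0L]) - 2 * p$noise_sd)
})

test_that("a gray level missing for a present class is a clear error", {
  p <- phantom_params(day = "1", scale = "lobe", grid_shape = 48, seed = 1,
                      gray_levels = c(parenchyma = 120, portal = 25,
                                      central = 25))
  tr <- build_vessel_trees(p)
  zones <- equal_volume_zonation(tr$labels == 0L, tr$labels == 2L,
                                 tr$labels == 1L, p$voxel_size_um)
  tr <- place_infarcts(p, tr, zones)
  expect_error(render_grayscale(tr, p), "infarct")
})

test_that("parameter validation rejects malformed presets", {
  expect_error(phantom_params(day = "1", zone_placement_weights =
                                c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(phantom_params(day = "1", confluent_fraction = 1.2),
               "\\[0, 1\\]")
  expect_error(phantom_params(day = "1", infarct_radius_um_range =
                                c(-1, 5)), "positive")
})

test_that("truth tables and labels survive a disk round trip", {
  ph <- generate_phantom(phantom_params(day = "1", scale = "lobe",
                                        grid_shape = 48, seed = 1),
                         render = FALSE)
  dir <- file.path(tempdir(), "truth_rt")
  write_truth(ph$truth, dir)
  lv <- read_volume(file.path(dir, "labels.tif"))
  expect_identical(array(as.integer(lv$data), dim(lv$data)),
                   ph$truth$labels)
  tab <- read.csv(file.path(dir, "infarcts.csv"))
  expect_equal(nrow(tab), nrow(ph$truth$infarct_table))
})

test_that("day-7 vessel trees reach all of a 256^3 parenchyma", {
  p <- phantom_params(day = "7", scale = "lobe", grid_shape = 256, seed = 3)
  tr <- build_vessel_trees(p)
  vessels <- array(tr$labels %in% 1:2, dim = dim(tr$labels))
  dist_vox <- infarct3d:::edt(vessels)
  expect_lt(max(dist_vox[tr$labels == 0L]), 40)
})

test_that("truth total infarct volume rises strictly across the days", {
  tot <- vapply(c("1", "3", "5", "7"), function(day) {
    ph <- generate_phantom(phantom_params(day = day, scale = "lobe",
                                          grid_shape = 128, seed = 11),
                           render = FALSE)
    sum(ph$truth$infarct_table$volume_um3)
  }, 0)
  expect_true(all(diff(tot) > 0))
})
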