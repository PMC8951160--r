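test_that("assign_z is k * dz", {
  expect_equal(assign_z(10, voxel_spacing(1, 1, 0.053)), 0.53)
  expect_equal(assign_z(1, voxel_spacing(1, 1, 44.2)), 44.2)
  k <- 1:50
  z <- assign_z(k, voxel_spacing(1, 1, 31.9))
  expect_equal(diff(z), rep(31.9, 49))
  expect_error(assign_z(0, voxel_spacing(1, 1, 1)))
})

test_that("direct reconstruction emits one point per (windowed) voxel", {
  sp <- voxel_spacing(2, 3, 5)
  sl <- function(m, k) slice_image(m, 8L, k)
  st <- slice_stack(list(sl(matrix(c(200L, 10L, 200L, 200L), 2, 2), 1),
                         sl(matrix(10L, 2, 2), 2)), sp)
  all_cloud <- direct_reconstruct(st, recon_config("direct", sp))
  expect_equal(n_points(all_cloud), 8L)
  expect_true(all(all_cloud$labels == "interior"))

  wood <- direct_reconstruct(st, recon_config("direct", sp,
                                              foreground = grey_window(150, 255)))
  expect_equal(n_points(wood), 3L)
  expect_equal(wood$greys, rep(200L, 3))
  # coordinate convention: x = (j-1) dx, y = (i-1) dy, z = k dz
  expect_equal(sort(wood$points[, "z"]), rep(5, 3))
  expect_true(all(wood$points[, "x"] %in% c(0, 2)) &&
                all(wood$points[, "y"] %in% c(0, 3)))

  air <- slice_stack(list(sl(matrix(10L, 4, 4), 1)), sp)
  expect_equal(n_points(direct_reconstruct(
    air, recon_config("direct", sp, foreground = grey_window(150, 255)))), 0L)
})

test_that("direct count on a phantom equals the ground-truth body voxel count", {
  ph <- generate_phantom(tiny_spec())
  cfg <- recon_config("direct", ph$stack$spacing, foreground = grey_window(100, 255))
  cloud <- direct_reconstruct(ph$stack, cfg)
  expect_equal(n_points(cloud), sum(ph$truth$body_mask))
})

test_that("segmented reconstruction labels pores and stays below direct size", {
  spp <- phantom_spec(grid = c(48L, 48L, 48L), spacing = voxel_spacing(25, 25, 25),
                      body = list(a = 500, b = 500, c = 500, taper = 0),
                      cracks = list(), pores = list(count = 1L, radius = c(120, 120)),
                      noise_sd = 0, seed = 3L)
  ph <- generate_phantom(spp)
  cloud <- segmented_reconstruct(ph$stack, seg_cfg(spp$spacing))
  feat <- cloud$points[cloud$labels == "internal_feature", , drop = FALSE]
  expect_gt(nrow(feat), 0)
  pore <- ph$truth$pores[[1]]
  # per intersected slice the feature points form a ring around the pore axis
  ks <- sort(unique(round(feat[, 3] / spp$spacing$dz)))
  mid_k <- ks[ceiling(length(ks) / 2)]
  ring <- feat[round(feat[, 3] / spp$spacing$dz) == mid_k, , drop = FALSE]
  expect_gt(nrow(ring), 4)
  centroid <- colMeans(ring)
  expect_lt(abs(centroid[1] - pore$x), spp$spacing$dx)
  expect_lt(abs(centroid[2] - pore$y), spp$spacing$dy)

  direct_all <- direct_reconstruct(ph$stack, recon_config("direct", spp$spacing))
  expect_lt(n_points(cloud), n_points(direct_all))
})

test_that("segmented reconstruction without features yields no feature points", {
  spc <- tiny_spec()
  spc$cracks <- list()
  spc$pores$count <- 0L
  ph <- generate_phantom(spc)
  cloud <- segmented_reconstruct(ph$stack, seg_cfg(spc$spacing))
  expect_equal(sum(cloud$labels == "internal_feature"), 0L)
  expect_gt(sum(cloud$labels == "outer_surface"), 0L)
})

test_that("segmented reconstruction warns and returns empty on all-air stacks", {
  sp <- voxel_spacing(1, 1, 1)
  st <- slice_stack(list(slice_image(matrix(20L, 24, 24), 8L)), sp)
  expect_warning(cloud <- segmented_reconstruct(st, seg_cfg(sp, air_threshold = 100)),
                 "no object found")
  expect_equal(n_points(cloud), 0L)
})

test_that("every point carries exactly one label and clouds are deterministic", {
  ph <- generate_phantom(tiny_spec(noise_sd = 4))
  cloud1 <- segmented_reconstruct(ph$stack, seg_cfg(ph$stack$spacing))
  cloud2 <- segmented_reconstruct(ph$stack, seg_cfg(ph$stack$spacing))
  expect_identical(cloud1$points, cloud2$points)
  expect_identical(cloud1$labels, cloud2$labels)
  expect_true(all(cloud1$labels %in% c("interior", "outer_surface",
                                       "internal_feature", "wood_boundary")))
  # one label per voxel: no duplicated coordinates
  expect_false(any(duplicated(cloud1$points)))
})

test_that("z extent of a full-depth reconstruction is (n_slices - 1) * dz", {
  sp <- voxel_spacing(1, 1, 44.2)
  slices <- lapply(1:9, function(k) slice_image(matrix(200L, 4, 4), 8L, k))
  st <- slice_stack(slices, sp)
  cloud <- direct_reconstruct(st, recon_config("direct", sp))
  expect_equal(diff(range(cloud$points[, "z"])), 8 * 44.2)
})

test_that("apply_tilt is a rigid z-rotation with group structure", {
  ph <- generate_phantom(tiny_spec())
  cloud <- segmented_reconstruct(ph$stack, seg_cfg(ph$stack$spacing))
  expect_identical(apply_tilt(cloud, 0), cloud)
  full <- apply_tilt(cloud, 360)
  expect_equal(full$points, cloud$points, tolerance = 1e-9)
  twice90 <- apply_tilt(apply_tilt(cloud, 90), 90)
  once180 <- apply_tilt(cloud, 180)
  expect_equal(twice90$points, once180$points, tolerance = 1e-9)
  expect_identical(twice90$labels, cloud$labels)
})

test_that("recon_config validates its invariants", {
  sp <- voxel_spacing(1, 1, 1)
  expect_error(recon_config("segmented", sp), "feature_window")
  expect_error(recon_config("direct", sp, tilt_deg = 200), "tilt")
  expect_error(recon_config("direct", sp, tilt_deg = -180), "tilt")
})
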