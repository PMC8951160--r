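test_that("percent_change reproduces the published worked examples", {
  expect_equal(percent_change(155606, 160958), 3.44)
  expect_equal(percent_change(70653.6, 80404.1), 13.80)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "strictly positive")
  # index = 100 + percent, exactly
  set.seed(31)
  for (i in 1:20) {
    r <- runif(1, 1, 1e6); cur <- runif(1, 1, 1e6)
    expect_identical(change_index(r, cur), 100 + percent_change(r, cur))
  }
})

test_that("change_table reproduces both published baselines", {
  reps <- palaeo_point_reports()
  t09 <- change_table(reps, base = "2009")
  len09 <- t09[t09$quantity == "length", ]
  expect_equal(len09$percent[match(c("2013", "2015", "2017", "2018"), len09$label)],
               c(3.44, -1.86, -2.47, -3.32))
  expect_equal(len09$index[match("2009", len09$label)], 100)
  expect_equal(len09$percent[match("2009", len09$label)], 0)

  t13 <- change_table(reps, base = "2013")
  th13 <- t13[t13$quantity == "thickness", ]
  expect_equal(th13$percent[match(c("2015", "2017", "2018"), th13$label)],
               c(-17.20, -18.14, -21.25))
  expect_error(change_table(reps, base = "1999"), "unknown base")
  expect_error(change_table(reps[1], base = "2009"), "at least two")
})

test_that("bounding_dimensions handles axis-aligned and rotated cubes", {
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  cube <- point_cloud(corners)
  expect_equal(unname(bounding_dimensions(cube, "pca")), c(1, 1, 1), tolerance = 1e-6)
  expect_equal(unname(bounding_dimensions(cube, "axis")), c(1, 1, 1))

  rot <- point_cloud(corners %*% t(rot_z(45)))
  expect_equal(unname(bounding_dimensions(rot, "pca")), c(1, 1, 1), tolerance = 1e-6)
  expect_equal(unname(bounding_dimensions(rot, "axis")),
               c(sqrt(2), sqrt(2), 1), tolerance = 1e-9)

  flat <- point_cloud(cbind(runif(10), runif(10), 0))
  expect_warning(bounding_dimensions(flat, "pca"), "degenerate")
})

test_that("phantom cloud pca length matches the spec major axis", {
  spc <- tiny_spec()
  spc$cracks <- list(); spc$pores$count <- 0L
  ph <- generate_phantom(spc)
  cloud <- segmented_reconstruct(ph$stack, seg_cfg(spc$spacing))
  dims <- bounding_dimensions(cloud, "pca")
  tol <- 2 * max(spc$spacing$dx, spc$spacing$dy, spc$spacing$dz)
  expect_lt(abs(dims[1] - ph$truth$major_axis_length), tol)
})

test_that("voxel_volume is the count times the voxel volume, linearly", {
  expect_equal(voxel_volume(8, voxel_spacing(1, 1, 1)), 8)
  expect_equal(voxel_volume(0, voxel_spacing(3, 4, 5)), 0)
  sp <- voxel_spacing(2, 3, 5)
  expect_equal(voxel_volume(7, sp), 7 * 30)
  expect_equal(voxel_volume(14, sp), 2 * voxel_volume(7, sp))
  expect_equal(voxel_volume(7, voxel_spacing(4, 3, 5)), 2 * voxel_volume(7, sp))
})

test_that("nearest_distances equals the brute-force O(N^2) oracle", {
  set.seed(41)
  a <- matrix(runif(600, 0, 100), 200, 3)
  b <- matrix(runif(600, 0, 100), 200, 3)
  df <- nearest_distances(point_cloud(a), point_cloud(b))
  brute <- apply(a, 1, function(p) sqrt(min(colSums((t(b) - p)^2))))
  expect_equal(df$distances, brute, tolerance = 1e-12)

  self <- nearest_distances(point_cloud(a), point_cloud(a))
  expect_true(all(self$distances == 0))
})

test_that("nearest_distances respects translation geometry bounds", {
  g <- as.matrix(expand.grid(x = seq(0, 100, 2), y = seq(0, 100, 2), z = 0))
  ref <- point_cloud(sweep(g, 2, c(5, 0, 0), `+`))
  df <- nearest_distances(point_cloud(g), ref)
  expect_lte(max(df$distances), 5)
  expect_gte(max(df$distances), 5 - 2)
  expect_error(nearest_distances(point_cloud(g), point_cloud(NULL)), "empty")
})

test_that("icp_align recovers identity and planted rigid motions", {
  ph <- generate_phantom(tiny_spec())
  cloud <- segmented_reconstruct(ph$stack, seg_cfg(ph$stack$spacing))
  set.seed(42)
  keep <- sample(n_points(cloud), 1000)
  mv <- point_cloud(cloud$points[keep, ], cloud$labels[keep])

  same <- icp_align(mv, mv)
  expect_equal(same$rms, 0, tolerance = 1e-9)
  expect_equal(rotation_angle_deg(same$transform), 0, tolerance = 1e-6)

  fx <- point_cloud(sweep(mv$points %*% t(rot_z(5)), 2, c(10, 5, 0), `+`))
  fit <- icp_align(mv, fx)
  expect_lt(abs(rotation_angle_deg(fit$transform) - 5), 0.1)
  expect_lt(max(abs(fit$transform$translation - c(10, 5, 0))), 0.5)
  expect_true(fit$converged)
  # rms trace is non-increasing
  expect_true(all(diff(fit$rms_trace) <= 1e-12))
})

test_that("icp rms reaches the expected noise floor under jitter", {
  ph <- generate_phantom(tiny_spec())
  cloud <- segmented_reconstruct(ph$stack, seg_cfg(ph$stack$spacing))
  set.seed(43)
  keep <- sample(n_points(cloud), 1500)
  mv <- point_cloud(cloud$points[keep, ])
  sigma <- 1
  fx <- point_cloud(mv$points + matrix(rnorm(3 * 1500, sd = sigma), ncol = 3))
  fit <- icp_align(mv, fx)
  floor_rms <- sigma * sqrt(3)  # per-point 3-d Gaussian displacement
  expect_lt(abs(fit$rms - floor_rms) / floor_rms, 0.5)
})

test_that("rigid_transform validates orthonormality", {
  expect_error(rigid_transform(matrix(2 * diag(3), 3)), "orthonormal")
  tr <- rigid_transform(rot_z(30), c(1, 2, 3))
  p <- matrix(rnorm(30), 10, 3)
  back <- transform_cloud(point_cloud(p), tr)
  expect_equal(back$points, sweep(p %*% t(rot_z(30)), 2, c(1, 2, 3), `+`),
               ignore_attr = TRUE)
})
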