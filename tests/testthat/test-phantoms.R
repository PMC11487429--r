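test_that("NEMA IQ phantom: ratio, volumes, layout", {
  ph <- nema_iq_phantom()
  expect_equal(attr(ph, "ratio"), 21.25 / 5.3, tolerance = 1e-9)
  expect_equal(attr(ph, "ratio"), 4, tolerance = 0.01)
  expect_equal(attr(ph, "sphere_diameters"), c(10, 13, 17, 22, 28, 37))
  expect_true(all(abs(sqrt(rowSums(attr(ph, "sphere_centers")[, 1:2]^2)) - 57.2) < 1e-9))
  # interior ~9.8 L torso
  act <- phantom_activity(ph)          # Bq; conc 5.3 kBq/mL = 5.3 Bq/mm^3
  vol_bg_L <- act / 5.3 / 1e6          # spheres add ~1%
  expect_gt(vol_bg_L, 9)
  expect_lt(vol_bg_L, 11)
})

test_that("point source grid spans the first octant", {
  phs <- point_source_grid()
  pos <- attr(phs, "positions")
  expect_length(phs, 125)
  expect_equal(unname(pos[which.max(rowSums(pos)), ]), c(148, 148, 148))
  expect_true(any(apply(pos, 1, function(p) all(p == c(37, 0, 0)))))
  p1 <- point_source_grid(n_per_axis = 1)
  expect_equal(unname(attr(p1, "positions")[1, ]), c(0, 0, 0))
})

test_that("point source with background: activities resolve the swapped labels", {
  ph <- point_source_with_background(c(10, 0, 0))
  a <- phantom_activity(ph)
  expect_equal(a, 28870, tolerance = 1e-3)  # 28.8 kBq cube + 70 Bq source
  # cube concentration 0.45 kBq/mL; source 16.7 MBq/mL
  expect_equal(ph$primitives[[1]]$activity, 0.45, tolerance = 1e-9)
  expect_equal(ph$primitives[[2]]$activity / 1e3, 16.7, tolerance = 0.01)
  bare <- point_source_with_background(bg_activity_kBq = 0)
  expect_length(bare$primitives, 1)
})

test_that("normalization cube and NECR phantom bookkeeping", {
  nc <- normalization_cube(activity_kBq_mL = 2)
  expect_equal(phantom_activity(nc), 2 * 46656 * 1e3 / 1e3 * 1e3) # 2 kBq/mL * 46.656 L
  np <- necr_phantom(activity_kBq_mL = 10)
  expect_equal(attr(np, "total_kBq"), 10 * pi * 100^2 * 700 / 1e3, tolerance = 1e-9)
  expect_equal(phantom_activity(np) / 1e3, attr(np, "total_kBq"), tolerance = 1e-3)
  expect_equal(primitive_volume <- pi * 1.6^2 * 700,
               pi * 0.16^2 * 70 * 1e3, tolerance = 1e-9) # line volume in mm^3
})

test_that("emission sampling matches activity-volume proportions", {
  set.seed(21)
  # two equal-volume primitives, concentration 1:3
  ph <- analytic_phantom(list(
    prim_box(c(-20, 0, 0), 10, activity_kBq_mL = 1),
    prim_box(c(20, 0, 0), 10, activity_kBq_mL = 3)), "air")
  pts <- sample_emission(ph, 20000)
  frac <- mean(pts[, 1] > 0)
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / 20000))
  # uniformity in a sphere: radial CDF ~ (r/R)^3
  sph <- analytic_phantom(list(prim_sphere(c(0, 0, 0), 10, 1)), "air")
  p <- sample_emission(sph, 20000)
  r <- sqrt(rowSums(p^2))
  ks <- suppressWarnings(stats::ks.test(r, function(q) (q / 10)^3))
  expect_gt(ks$p.value, 0.001)
  # point source: all points within the source radius
  ps <- point_source_with_background(c(5, 5, 5), bg_activity_kBq = 0)
  q <- sample_emission(ps, 500)
  expect_true(all(sqrt(rowSums((q - matrix(c(5, 5, 5), 500, 3, TRUE))^2)) <= 0.1 + 1e-12))
})

test_that("override order removes overlapped activity", {
  set.seed(22)
  # hot box overridden by a cold sphere in its center
  ph <- analytic_phantom(list(
    prim_box(c(0, 0, 0), 20, activity_kBq_mL = 1),
    prim_sphere(c(0, 0, 0), 5, activity_kBq_mL = 0)), "air")
  pts <- sample_emission(ph, 5000)
  expect_true(all(sqrt(rowSums(pts^2)) > 5))
  expect_equal(phantom_activity(ph), 20^3 - 4 / 3 * pi * 125, tolerance = 0.02)
})

test_that("voxelization conserves total activity and reproduces constants", {
  g <- image_grid_centered(1, 24)
  cube <- analytic_phantom(list(prim_box(c(0, 0, 0), 20, activity_kBq_mL = 2)), "air")
  v <- voxelize(cube, g, supersample = 2)
  inside <- v$data[abs(grid_centers(g, 1)) < 9,
                   abs(grid_centers(g, 2)) < 9, abs(grid_centers(g, 3)) < 9]
  expect_true(all(inside == 2))
  expect_equal(sum(v$data) * g$voxel^3, phantom_activity(cube), tolerance = 5e-3)
  sph <- analytic_phantom(list(prim_sphere(c(0, 0, 0), 7, 3)), "air")
  vs <- voxelize(sph, image_grid_centered(1, 20), supersample = 4)
  expect_equal(sum(vs$data), 3 * 4 / 3 * pi * 343, tolerance = 5e-3)
  empty <- analytic_phantom(list(prim_box(c(0, 0, 0), 5, 0)), "air")
  expect_true(all(voxelize(empty, g)$data == 0))
})

test_that("derenzo phantom has six sectors of distinct rod diameters", {
  ph <- derenzo_phantom()
  radii <- vapply(ph$primitives[-1], function(p) p$dims[1], 0)
  expect_equal(sort(unique(radii)), c(2, 2.5, 3, 4, 5, 6) / 2)
  expect_gt(length(radii), 20)
})
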