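test_that("geometry invariants hold and bad geometries are rejected", {
  geom <- phantom_geometry()
  vol_cm3 <- 7 * pi * geom$syringe_radius^2 * geom$syringe_length / 1000
  expect_lt(abs(vol_cm3 - 145) / 145, 0.10)
  # inserts must fit in the cylinder
  expect_error(phantom_geometry(insert_offset = 95), "fit")
  # overlapping syringes (radius too large for the pitch circle)
  expect_error(phantom_geometry(syringe_radius = 12, syringe_length = 46),
               "overlap")
  expect_error(phantom_geometry(voxel_spacing = 0))
})

test_that("insert configs enforce the four canonical shapes", {
  expect_equal(insert_config(1)$syringe_activities, rep(40, 7))
  expect_equal(sum(is.na(insert_config(2)$syringe_activities)), 1)
  hot3 <- insert_config(3)$syringe_activities
  expect_setequal(unique(hot3), c(20, 40, 80))
  expect_equal(max(hot3) / min(hot3), 4)
  hot4 <- insert_config(4)$syringe_activities
  expect_equal(sum(is.na(hot4)), 1)
  expect_equal(max(hot4, na.rm = TRUE) / min(hot4, na.rm = TRUE), 4)
  expect_error(insert_config(5))
  expect_error(insert_config(1, c(40, 40, 40)), "7 entries")
  expect_error(insert_config(3, c(40, 80, 10, 80, 20, 80, 20)), "ratio")
  expect_error(insert_config(1, c(NA, rep(40, 6))), "necrotic")
})

test_that("voxelization assigns syringe, background and outside values", {
  geom <- phantom_geometry()
  m1 <- make_roi_mask(geom, 1)
  v1 <- build_activity_volume(geom, insert_config(1))
  expect_equal(unique(v1$data[m1$data]), 40)
  ax <- radstab:::grid_axes(geom)
  outside <- outer(ax$x^2, ax$y^2, "+") > geom$cylinder_radius^2
  expect_true(all(v1$data[rep(outside, length(ax$z))] == 0))
  in_cyl_not_syr <- !m1$data & rep(!outside, length(ax$z))
  expect_equal(unique(v1$data[in_cyl_not_syr]), geom$background_activity)

  v3 <- build_activity_volume(geom, insert_config(3))
  m3 <- make_roi_mask(geom, 3)
  expect_setequal(unique(v3$data[m3$data]), c(20, 40, 80))

  # degenerate phantom: activities equal to background -> constant cylinder
  vb <- build_activity_volume(geom, insert_config(1, rep(5, 7)))
  expect_equal(unique(vb$data[rep(!outside, length(ax$z))]), 5)
})

test_that("necrotic syringes image as background", {
  geom <- phantom_geometry()
  v2 <- build_activity_volume(geom, insert_config(2), insert_index = 2)
  m2 <- make_roi_mask(geom, 2)
  expect_setequal(unique(v2$data[m2$data]), c(5, 40))
})

test_that("activity is conserved under center-point voxelization", {
  geom <- phantom_geometry()
  v1 <- build_activity_volume(geom, insert_config(1))
  m1 <- make_roi_mask(geom, 1)
  vox <- geom$voxel_spacing^3
  insert_vol <- 7 * pi * geom$syringe_radius^2 * geom$syringe_length
  water_vol <- pi * geom$cylinder_radius^2 * geom$cylinder_length - insert_vol
  expected <- 40 * insert_vol + 5 * water_vol
  expect_lt(abs(sum(v1$data) * vox - expected) / expected, 0.10)
})

test_that("ROI mask volume, translation invariance and containment", {
  geom <- phantom_geometry()
  m1 <- make_roi_mask(geom, 1)
  vol_cm3 <- m1$voxel_count * geom$voxel_spacing^3 / 1000
  expect_lt(abs(vol_cm3 - 145) / 145, 0.10)
  # mirrored mounting positions give identical voxel counts
  m3 <- make_roi_mask(geom, 3)
  expect_equal(m1$voxel_count, m3$voxel_count)
  expect_equal(make_roi_mask(geom, 2)$voxel_count,
               make_roi_mask(geom, 4)$voxel_count)
  # entirely inside the cylinder
  ax <- radstab:::grid_axes(geom)
  inside <- outer(ax$x^2, ax$y^2, "+") <= geom$cylinder_radius^2
  expect_true(all(rep(inside, length(ax$z))[m1$data]))
  expect_error(make_roi_mask(geom, 9), "out of range")
})

test_that("phantom build rejects mismatched configs", {
  geom <- phantom_geometry()
  expect_error(build_phantom(geom, lapply(1:4, insert_config), 1:3), "one mounting")
  cfg <- insert_config(1)
  cfg$syringe_activities <- rep(40, 6)
  expect_error(build_phantom(geom, list(cfg)), "syringe count mismatch")
})
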