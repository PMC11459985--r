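test_that("GLCM on a 1x1x4 line matches hand-enumerated pair counts", {
  lev <- array(c(1L, 1L, 2L, 2L), c(1, 1, 4))
  droi <- droi_from_levels(lev, ng = 2)
  f <- glcm_features(droi, distance = 1,
                     directions = matrix(c(0, 0, 1), 1))
  # 6 symmetric pairs: (1,1)x2, (1,2), (2,1), (2,2)x2
  expect_equal(unname(f["glcm_joint_maximum"]), 1 / 3)
  expect_equal(unname(f["glcm_difference_average"]), 1 / 3)
  expect_equal(unname(f["glcm_dissimilarity"]), 1 / 3)
})

test_that("GLCM of a constant ROI collapses to a single cell", {
  lev <- array(1L, c(3, 3, 3))
  f <- glcm_features(droi_from_levels(lev, ng = 1))
  expect_equal(unname(f["glcm_joint_maximum"]), 1)
  expect_equal(unname(f["glcm_difference_average"]), 0)
  expect_equal(unname(f["glcm_contrast"]), 0)
})

test_that("merged GLCM is symmetric and normalized on random ROIs", {
  for (s in 1:5) {
    droi <- random_droi(c(5, 4, 3), ng = 4, seed = s)
    m <- radstab:::glcm_matrix(radstab:::crop_levels(droi), droi$ng)
    expect_equal(m, t(m))
    expect_gt(sum(m), 0)
    p <- m / sum(m)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("merged GLCM features are invariant to 90-degree grid rotation", {
  # rotate about the z axis: new[x,y,z] = old[y, nx+1-x, z]
  rot_z <- function(lev) {
    d <- dim(lev)
    out <- aperm(lev, c(2, 1, 3))[, d[1]:1, , drop = FALSE]
    dim(out) <- d[c(2, 1, 3)]
    out
  }
  for (s in c(11, 12)) {
    droi <- random_droi(c(4, 5, 3), ng = 4, seed = s)
    droi_rot <- droi_from_levels(rot_z(droi$levels), droi$ng)
    expect_equal(glcm_features(droi_rot), glcm_features(droi),
                 tolerance = 1e-12)
    expect_equal(glrlm_features(droi_rot), glrlm_features(droi),
                 tolerance = 1e-12)
  }
})

test_that("GLCM with an isolated-voxel ROI is a degenerate error", {
  lev <- array(NA_integer_, c(3, 3, 3))
  lev[1, 1, 1] <- 1L
  lev[3, 3, 3] <- 2L  # no pair at distance 1
  expect_error(glcm_features(droi_from_levels(lev, 2), distance = 1),
               "degenerate")
})
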