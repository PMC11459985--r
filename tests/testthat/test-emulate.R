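small_geom <- function() phantom_geometry(voxel_spacing = 4)

test_that("zero PSF, zero noise and zero filter is the identity", {
  vol <- build_activity_volume(small_geom(), insert_config(1))
  nm <- noise_model(psf_fwhm = 0, base_sd = 0)
  st <- recon_setting(filter_fwhm = 0)
  out <- emulate_reconstruction(vol, st, nm, seed = 1)
  expect_equal(out$data, vol$data)
})

test_that("emulation is deterministic and leaves the caller's RNG alone", {
  vol <- build_activity_volume(small_geom(), insert_config(1))
  set.seed(99)
  before <- .Random.seed
  a <- emulate_reconstruction(vol, recon_setting(), seed = 42)
  expect_identical(before, .Random.seed)
  b <- emulate_reconstruction(vol, recon_setting(), seed = 42)
  expect_identical(a$data, b$data)
  c_ <- emulate_reconstruction(vol, recon_setting(), seed = 43)
  expect_false(identical(a$data, c_$data))
})

test_that("noise SD grows with the iteration-subset product and drops with TOF", {
  geom <- small_geom()
  vol <- build_activity_volume(geom, insert_config(1))
  mask <- make_roi_mask(geom, 1)
  nm <- noise_model(psf_fwhm = 0)
  low <- recon_setting(subsets = 24, iterations = 2, filter_fwhm = 0)
  high <- recon_setting(subsets = 24, iterations = 6, filter_fwhm = 0)
  sd_of <- function(st, seeds) {
    imgs <- vapply(seeds, function(s)
      emulate_reconstruction(vol, st, nm, seed = s)$data[mask$data],
      numeric(mask$voxel_count))
    mean(apply(imgs, 1, sd))
  }
  seeds <- 1:20
  sd_low <- sd_of(low, seeds)
  sd_high <- sd_of(high, seeds)
  expect_gt(sd_high, sd_low)
  # scaling law: sqrt(144/48) = sqrt(3), Monte-Carlo tolerance 10%
  expect_lt(abs(sd_high / sd_low - sqrt(3)), 0.1 * sqrt(3))
  # TOF divides the noise SD by the gain factor
  tof_off <- recon_setting(filter_fwhm = 0, tof = FALSE)
  tof_on <- recon_setting(filter_fwhm = 0, tof = TRUE)
  expect_lt(abs(sd_of(tof_off, seeds) / sd_of(tof_on, seeds) - 1.35),
            0.1 * 1.35)
})

test_that("stronger post-filtering strictly lowers noise-free in-ROI variance", {
  geom <- small_geom()
  vol <- build_activity_volume(geom, insert_config(3), insert_index = 3)
  mask <- make_roi_mask(geom, 3)
  nm <- noise_model(base_sd = 0)
  v <- vapply(c(0, 2, 4, 7), function(fw)
    var(emulate_reconstruction(vol, recon_setting(filter_fwhm = fw),
                               nm, seed = 1)$data[mask$data]), 0)
  expect_true(all(diff(v) < 0))
})

test_that("invalid degradation parameters are rejected", {
  expect_error(noise_model(psf_fwhm = -1), "negative PSF")
  expect_error(recon_setting(filter_fwhm = -0.5), "negative filter")
})
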