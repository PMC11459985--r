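# Image-space surrogate for iterative PET reconstruction.
#
# True list-mode OSEM is out of scope; instead the chain is
#   PSF blur -> additive Gaussian noise (scaled by the subset*iteration
#   product, damped by TOF) -> Gaussian post-filter -> clip at 0,
# which reproduces the qualitative behaviour that matters for texture
# stability: noise grows with the update product, TOF improves SNR, and the
# post-filter trades resolution for smoothness.

#' Noise and resolution model for the reconstruction surrogate
#'
#' @param psf_fwhm Intrinsic scanner point-spread FWHM in mm applied before
#'   noise (0 disables).
#' @param base_sd Noise standard deviation (kBq/ml) at the default
#'   subsets-times-iterations product; default 0.5 = 10% of the 5 kBq/ml
#'   water background.
#' @param reference_product Subsets x iterations product at which `base_sd`
#'   applies (default 24 x 2 = 48).
#' @param tof_gain Factor by which TOF divides the noise standard deviation.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(psf_fwhm = 5, base_sd = 0.5,
                        reference_product = 48, tof_gain = 1.35) {
  if (psf_fwhm < 0) stop("parameter error: negative PSF FWHM")
  stopifnot(base_sd >= 0, reference_product > 0, tof_gain >= 1)
  structure(list(psf_fwhm = psf_fwhm, base_sd = base_sd,
                 reference_product = reference_product, tof_gain = tof_gain),
            class = "noise_model")
}

# Separable 3D Gaussian blur, FWHM in mm on an isotropic grid.
# Edge handling: the truncated kernel is renormalized per voxel, so constant
# regions stay constant.
gaussian_blur3d <- function(a, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(a)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing  # voxels
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  for (axis in 1:3) a <- convolve_axis(a, k, axis)
  a
}

# 1D convolution along one axis of a 3D array via banded-matrix multiply.
convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- d[axis]
  r <- (length(k) - 1L) / 2L
  band <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    i <- seq_len(n)
    ok <- i + j >= 1 & i + j <= n
    band[cbind(i[ok], (i + j)[ok])] <- k[j + r + 1]
  }
  band <- band / rowSums(band)  # renormalize truncated edges
  m <- band %*% matrix(ap, nrow = n)
  aperm(array(m, dim = d[perm]), order(perm))
}

#' Apply the reconstruction surrogate to an activity volume
#'
#' Deterministic given `(volume, setting, noise_model, seed)`: blurs with
#' the intrinsic PSF, adds zero-mean Gaussian noise with standard deviation
#' `base_sd * sqrt(subsets x iterations / reference_product)`, divided by
#' `tof_gain` when TOF is on, applies a Gaussian post-filter of FWHM
#' `setting$filter_fwhm` (0 = none), and clips negatives to zero. The
#' caller's RNG state is left untouched.
#'
#' @param volume An `activity_volume`.
#' @param setting A [recon_setting()].
#' @param noise A [noise_model()].
#' @param seed Integer seed for the noise realization.
#' @return An `activity_volume` of the same dimensions.
#' @examples
#' vol <- build_activity_volume(phantom_geometry(voxel_spacing = 4),
#'                              insert_config(1))
#' img <- emulate_reconstruction(vol, recon_setting(), noise_model(), seed = 1)
#' @export
emulate_reconstruction <- function(volume, setting, noise = noise_model(),
                                   seed = 1L) {
  stopifnot(inherits(volume, "activity_volume"),
            inherits(setting, "recon_setting"),
            inherits(noise, "noise_model"))
  if (setting$filter_fwhm < 0) stop("parameter error: negative filter FWHM")
  a <- gaussian_blur3d(volume$data, noise$psf_fwhm, volume$spacing)
  sd_noise <- noise$base_sd *
    sqrt(setting$subsets * setting$iterations / noise$reference_product)
  if (setting$tof) sd_noise <- sd_noise / noise$tof_gain
  if (sd_noise > 0) {
    a <- a + with_local_seed(seed, array(stats::rnorm(length(a), 0, sd_noise),
                                         dim = dim(a)))
  }
  a <- gaussian_blur3d(a, setting$filter_fwhm, volume$spacing)
  a[a < 0] <- 0
  new_activity_volume(a, volume$spacing, volume$origin)
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
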