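# NIfTI input/output and grid resampling.

#' Write an activity volume or ROI mask as NIfTI
#'
#' @param x An `activity_volume` or `roi_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path) {
  stopifnot(inherits(x, "activity_volume") || inherits(x, "roi_mask"))
  dat <- if (is.logical(x$data)) array(as.integer(x$data), dim(x$data)) else x$data
  img <- RNifti::asNifti(dat)
  img <- RNifti::`pixdim<-`(img, rep(x$spacing, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as an activity volume
#'
#' @param path NIfTI file path.
#' @return An `activity_volume` (isotropy is not required here; use
#'   [resample_volume()] before feature extraction if spacing is
#'   anisotropic).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  a <- array(as.numeric(img), dim = dim(img)[1:3])
  structure(list(data = a, spacing = sp, origin = c(0, 0, 0)),
            class = "activity_volume")
}

#' Read a NIfTI mask as an ROI mask
#'
#' Nonzero voxels are in-mask.
#'
#' @param path NIfTI file path.
#' @return A `roi_mask`.
#' @export
read_mask_nifti <- function(path) {
  v <- read_volume_nifti(path)
  new_roi_mask(v$data != 0, spacing = v$spacing, origin = v$origin)
}

# Trilinear resampling of a 3D array from spacing `from` to isotropic `to`
# (mm). Sample positions are voxel centres of the output grid expressed in
# the input's continuous index space; edges clamp.
resample_array_trilinear <- function(a, from, to) {
  from <- rep(from, length.out = 3)
  d <- dim(a)
  nd <- pmax(1L, round(d * from / to))
  # output voxel-centre positions in input index units (1-based centres)
  pos <- lapply(1:3, function(ax) {
    ((seq_len(nd[ax]) - 0.5) * to / from[ax]) + 0.5
  })
  out <- array(0, dim = nd)
  i0 <- lapply(1:3, function(ax) {
    pmin(pmax(floor(pos[[ax]]), 1L), max(d[ax] - 1L, 1L))
  })
  fr <- lapply(1:3, function(ax) pmin(pmax(pos[[ax]] - i0[[ax]], 0), 1))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- pmin(i0[[1]] + dx, d[1]); iy <- pmin(i0[[2]] + dy, d[2])
    iz <- pmin(i0[[3]] + dz, d[3])
    wx <- if (dx == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (dy == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (dz == 0) 1 - fr[[3]] else fr[[3]]
    out <- out + outer(outer(wx, wy), wz) *
      array(a[ix, iy, iz], dim = nd)
  }
  out
}

#' Resample a volume (trilinear) or mask (nearest neighbour) to isotropic
#' spacing
#'
#' @param x An `activity_volume` or `roi_mask`.
#' @param target_spacing Desired isotropic spacing in mm.
#' @return Object of the same class on the resampled grid.
#' @export
resample_volume <- function(x, target_spacing) {
  stopifnot(target_spacing > 0)
  sp <- rep(x$spacing, length.out = 3)
  if (all(abs(sp - target_spacing) < 1e-9)) return(x)
  if (is.logical(x$data)) {
    # nearest neighbour: round trilinear interpolation of the indicator
    a <- resample_array_trilinear(array(as.numeric(x$data), dim(x$data)),
                                  sp, target_spacing)
    new_roi_mask(a >= 0.5, spacing = target_spacing, origin = x$origin)
  } else {
    a <- resample_array_trilinear(x$data, sp, target_spacing)
    new_activity_volume(a, spacing = target_spacing, origin = x$origin)
  }
}
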