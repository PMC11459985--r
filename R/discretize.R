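# Fixed-bin-number intensity discretization and shared grid helpers for the
# texture-matrix builders.

#' Fixed-bin-number discretization of ROI intensities
#'
#' Maps in-mask intensities to integer grey levels `1..ng` over the in-ROI
#' min-max range: `level = floor(ng * (x - min) / (max - min)) + 1`, with
#' `x = max` clamped to `ng`. A constant ROI maps every voxel to level 1 and
#' is flagged degenerate. Fixed-bin-number discretization makes all texture
#' features invariant to positive affine rescaling of the intensities.
#'
#' @param volume An `activity_volume`.
#' @param mask A `roi_mask` on the same grid.
#' @param ng Number of grey levels (>= 2).
#' @return A `discretized_roi`: list with `levels` (integer array, `NA`
#'   outside the mask), `ng`, `mask`, and `degenerate` flag.
#' @examples
#' v <- structure(list(data = array(0:3, c(1, 1, 4)), spacing = 1,
#'                     origin = c(0, 0, 0)), class = "activity_volume")
#' m <- structure(list(data = array(TRUE, c(1, 1, 4)), spacing = 1,
#'                     origin = c(0, 0, 0), voxel_count = 4),
#'                class = "roi_mask")
#' discretize_fbn(v, m, ng = 4)$levels
#' @export
discretize_fbn <- function(volume, mask, ng = 64L) {
  stopifnot(inherits(volume, "activity_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("grid error: volume and mask dimensions differ")
  ng <- as.integer(ng)
  if (ng < 2) stop("parameter error: ng must be >= 2")
  inm <- mask$data
  if (!any(inm)) stop("empty mask")
  x <- volume$data[inm]
  rng <- range(x)
  lev <- array(NA_integer_, dim = dim(volume$data))
  degenerate <- rng[2] - rng[1] <= 0
  if (degenerate) {
    lev[inm] <- 1L
  } else {
    lev[inm] <- pmin(as.integer(floor(ng * (x - rng[1]) / (rng[2] - rng[1]))) + 1L,
                     ng)
  }
  structure(list(levels = lev, ng = ng, mask = mask, degenerate = degenerate),
            class = "discretized_roi")
}

#' Fixed-bin-size discretization of ROI intensities
#'
#' Maps in-mask intensities to integer grey levels with a fixed bin width
#' anchored at a fixed lower bound:
#' `level = floor((x - lower_bound) / bin_width) + 1`. Unlike
#' [discretize_fbn()], the level of a voxel does not depend on the in-ROI
#' intensity range, so level differences keep their meaning in intensity
#' units across regions: a wide-range heterogeneous region genuinely
#' occupies more levels than a narrow-range homogeneous one.
#'
#' @param volume An `activity_volume`.
#' @param mask A `roi_mask` on the same grid.
#' @param bin_width Bin width in intensity units (kBq/ml).
#' @param lower_bound Intensity mapped to the lower edge of level 1.
#' @return A `discretized_roi`; its `ng` is the highest occupied level.
#' @export
discretize_fbs <- function(volume, mask, bin_width = 1, lower_bound = 0) {
  stopifnot(inherits(volume, "activity_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("grid error: volume and mask dimensions differ")
  if (bin_width <= 0) stop("parameter error: bin_width must be > 0")
  inm <- mask$data
  if (!any(inm)) stop("empty mask")
  x <- volume$data[inm]
  if (any(x < lower_bound))
    stop("parameter error: intensities below the lower bound")
  lev <- array(NA_integer_, dim = dim(volume$data))
  lev[inm] <- as.integer(floor((x - lower_bound) / bin_width)) + 1L
  structure(list(levels = lev, ng = max(lev[inm]), mask = mask,
                 degenerate = length(unique(lev[inm])) < 2),
            class = "discretized_roi")
}

# The 13 unique 3D direction offsets (one per axis pair, up to sign).
offsets_13 <- function() {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[!(o[, 1] == 0 & o[, 2] == 0 & o[, 3] == 0), , drop = FALSE]
  keep <- o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
    (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0)
  unname(o[keep, , drop = FALSE])
}

# All 26 neighbour offsets.
offsets_26 <- function() {
  o <- offsets_13()
  rbind(o, -o)
}

# Shift a 3D array by `off` voxels: result[i] = a[i + off], NA where i + off
# falls outside.
shift_array <- function(a, off, fill = NA) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      dst[[ax]] <- seq_len(d[ax] - o)
      src[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      dst[[ax]] <- seq_len(d[ax] + o) - o
      src[[ax]] <- seq_len(d[ax] + o)
    }
    if (length(dst[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Crop a discretized ROI to the mask bounding box plus a 1-voxel margin of
# out-of-mask space. Texture matrices only see in-mask voxels, and the
# margin keeps border distances well defined, so features are unchanged.
crop_levels <- function(droi) {
  inm <- which(droi$mask$data, arr.ind = TRUE)
  lo <- apply(inm, 2, min)
  hi <- apply(inm, 2, max)
  lev <- droi$levels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- hi - lo + 1L
  dim(lev) <- d
  out <- array(NA_integer_, d + 2L)
  out[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- lev
  out
}
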