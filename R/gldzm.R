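# Grey-level distance-zone matrix (GLDZM). Zones are the same 26-connected
# components as the GLSZM; each zone is tabulated against the minimum
# city-block distance from any of its voxels to the first voxel outside the
# ROI (minimum distance 1, so border voxels count as distance 1).

# City-block distance map to the nearest out-of-mask voxel. `levels` must
# carry at least one out-of-mask (NA) voxel on every face of its bounding
# box (crop_levels guarantees this); the map is the free-space Manhattan
# distance, computed by iterative 6-neighbour relaxation.
distance_map_cityblock <- function(levels) {
  d6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  dist <- array(Inf, dim = dim(levels))
  dist[is.na(levels)] <- 0
  repeat {
    prev <- dist
    for (r in 1:6) {
      nb <- shift_array(dist, d6[r, ], fill = Inf)
      dist <- pmin(dist, nb + 1)
    }
    if (identical(dist, prev)) break
  }
  dist
}

# Zone-distance count matrix (ng x max distance).
gldzm_matrix <- function(levels, ng) {
  z <- label_zones(levels)
  dmap <- distance_map_cityblock(levels)
  dz <- vapply(split(dmap[z$voxel_index], z$membership), min, 0)
  dz <- pmax(as.integer(dz[as.character(seq_along(z$size))]), 1L)
  dmax <- max(dz)
  idx <- (dz - 1L) * ng + z$level
  matrix(tabulate(idx, nbins = ng * dmax), ng, dmax)
}

#' GLDZM features (16)
#'
#' Distance-zone features: the GLSZM zone partition tabulated against each
#' zone's minimum city-block distance to the ROI border. The zone count and
#' grey-level marginal are identical to the GLSZM by construction.
#'
#' @param droi A `discretized_roi`.
#' @return Named numeric vector of 16 features (prefix `gldzm_`).
#' @export
gldzm_features <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  lev <- crop_levels(droi)
  counts <- gldzm_matrix(lev, droi$ng)
  nv <- sum(!is.na(lev))
  f <- ldm_common_features(counts)
  c(gldzm_small_distance_emphasis = f$small,
    gldzm_large_distance_emphasis = f$large,
    gldzm_low_grey_level_zone_emphasis = f$low_gl,
    gldzm_high_grey_level_zone_emphasis = f$high_gl,
    gldzm_small_distance_low_grey_level_emphasis = f$small_low,
    gldzm_small_distance_high_grey_level_emphasis = f$small_high,
    gldzm_large_distance_low_grey_level_emphasis = f$large_low,
    gldzm_large_distance_high_grey_level_emphasis = f$large_high,
    gldzm_grey_level_non_uniformity = f$gln,
    gldzm_grey_level_non_uniformity_normalised = f$glnn,
    gldzm_zone_distance_non_uniformity = f$sn,
    gldzm_zone_distance_non_uniformity_normalised = f$snn,
    gldzm_zone_percentage = f$n / nv,
    gldzm_grey_level_variance = f$gl_var,
    gldzm_zone_distance_variance = f$size_var,
    gldzm_zone_distance_entropy = f$entropy)
}
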