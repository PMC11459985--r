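# Full 78-feature extraction: five texture-matrix families evaluated on a
# discretized ROI with the 3D "merged" aggregation (one matrix pooled over
# all 13 unique directions, distance 1).

#' Extraction parameters
#'
#' @param ng Number of grey levels for fixed-bin-number discretization.
#' @param target_spacing Isotropic voxel spacing (mm) to which inputs are
#'   resampled before extraction (trilinear for volumes, nearest neighbour
#'   for masks); inputs already on this spacing are used as-is.
#' @param distance GLCM pair distance in voxels.
#' @param discretization `"fbn"` (fixed bin number over the in-ROI range,
#'   the default) or `"fbs"` (fixed bin size anchored at `lower_bound`).
#' @param bin_width Bin width in intensity units (FBS mode).
#' @param lower_bound Intensity at the lower edge of level 1 (FBS mode).
#' @return Object of class `extraction_params`.
#' @export
extraction_params <- function(ng = 64L, target_spacing = 2, distance = 1L,
                              discretization = c("fbn", "fbs"),
                              bin_width = 1, lower_bound = 0) {
  discretization <- match.arg(discretization)
  stopifnot(ng >= 2, target_spacing > 0, distance >= 1, bin_width > 0)
  structure(list(ng = as.integer(ng), target_spacing = target_spacing,
                 distance = as.integer(distance),
                 discretization = discretization, bin_width = bin_width,
                 lower_bound = lower_bound),
            class = "extraction_params")
}

#' Canonical names of the 78 features
#'
#' Ordered catalogue of the extracted features: 25 GLCM, 16 GLRLM, 16
#' GLSZM, 16 GLDZM and 5 NGTDM, with family prefixes.
#'
#' @return Character vector of length 78.
#' @export
feature_names <- function() {
  glcm <- c("joint_maximum", "joint_average", "joint_variance",
            "joint_entropy", "difference_average", "difference_variance",
            "difference_entropy", "sum_average", "sum_variance",
            "sum_entropy", "angular_second_moment", "contrast",
            "dissimilarity", "inverse_difference",
            "inverse_difference_normalised", "inverse_difference_moment",
            "inverse_difference_moment_normalised", "inverse_variance",
            "correlation", "autocorrelation", "cluster_tendency",
            "cluster_shade", "cluster_prominence",
            "information_correlation_1", "information_correlation_2")
  glrlm <- c("short_runs_emphasis", "long_runs_emphasis",
             "low_grey_level_run_emphasis", "high_grey_level_run_emphasis",
             "short_run_low_grey_level_emphasis",
             "short_run_high_grey_level_emphasis",
             "long_run_low_grey_level_emphasis",
             "long_run_high_grey_level_emphasis",
             "grey_level_non_uniformity",
             "grey_level_non_uniformity_normalised",
             "run_length_non_uniformity",
             "run_length_non_uniformity_normalised", "run_percentage",
             "grey_level_variance", "run_length_variance", "run_entropy")
  glszm <- c("small_zone_emphasis", "large_zone_emphasis",
             "low_grey_level_zone_emphasis", "high_grey_level_zone_emphasis",
             "small_zone_low_grey_level_emphasis",
             "small_zone_high_grey_level_emphasis",
             "large_zone_low_grey_level_emphasis",
             "large_zone_high_grey_level_emphasis",
             "grey_level_non_uniformity",
             "grey_level_non_uniformity_normalised",
             "zone_size_non_uniformity",
             "zone_size_non_uniformity_normalised", "zone_percentage",
             "grey_level_variance", "zone_size_variance",
             "zone_size_entropy")
  gldzm <- c("small_distance_emphasis", "large_distance_emphasis",
             "low_grey_level_zone_emphasis", "high_grey_level_zone_emphasis",
             "small_distance_low_grey_level_emphasis",
             "small_distance_high_grey_level_emphasis",
             "large_distance_low_grey_level_emphasis",
             "large_distance_high_grey_level_emphasis",
             "grey_level_non_uniformity",
             "grey_level_non_uniformity_normalised",
             "zone_distance_non_uniformity",
             "zone_distance_non_uniformity_normalised", "zone_percentage",
             "grey_level_variance", "zone_distance_variance",
             "zone_distance_entropy")
  ngtdm <- c("coarseness", "contrast", "busyness", "complexity", "strength")
  c(paste0("glcm_", glcm), paste0("glrlm_", glrlm),
    paste0("glszm_", glszm), paste0("gldzm_", gldzm),
    paste0("ngtdm_", ngtdm))
}

#' Extract all 78 texture features from a volume and mask
#'
#' Resamples volume and mask to the target isotropic spacing if needed,
#' discretizes in-mask intensities with a fixed bin number, and evaluates
#' the five texture-matrix families, returning the features in canonical
#' catalogue order.
#'
#' @param volume An `activity_volume`.
#' @param mask A `roi_mask` on the same grid.
#' @param params An [extraction_params()].
#' @return Named numeric vector of length 78.
#' @examples
#' geom <- phantom_geometry(voxel_spacing = 4)
#' vol <- build_activity_volume(geom, insert_config(3))
#' fv <- extract_all(vol, make_roi_mask(geom, 3),
#'                   extraction_params(target_spacing = 4))
#' length(fv)
#' @export
extract_all <- function(volume, mask, params = extraction_params()) {
  stopifnot(inherits(params, "extraction_params"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("grid error: volume and mask dimensions differ")
  volume <- resample_volume(volume, params$target_spacing)
  mask <- resample_volume(mask, params$target_spacing)
  droi <- if (identical(params$discretization, "fbs"))
    discretize_fbs(volume, mask, params$bin_width, params$lower_bound)
  else discretize_fbn(volume, mask, params$ng)
  out <- c(glcm_features(droi, distance = params$distance),
           glrlm_features(droi),
           glszm_features(droi),
           gldzm_features(droi),
           ngtdm_features(droi))
  stopifnot(identical(names(out), feature_names()))
  out
}
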