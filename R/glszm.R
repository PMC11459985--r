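# Grey-level size-zone matrix (GLSZM). Zones are 26-connected components
# of equal grey level, labelled as graph components (igraph).

# Label 26-connected equal-level zones. Returns a list with, per zone, its
# grey level and member linear indices (within `levels`).
label_zones <- function(levels) {
  inm <- which(!is.na(levels))
  if (length(inm) == 0) stop("empty mask")
  rank_of <- array(NA_integer_, dim = dim(levels))
  rank_of[inm] <- seq_along(inm)
  edges <- list()
  offs <- offsets_13()
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    nb_lev <- shift_array(levels, off)
    nb_rank <- shift_array(rank_of, off)
    ok <- !is.na(levels) & !is.na(nb_lev) & levels == nb_lev
    if (!any(ok)) next
    edges[[length(edges) + 1L]] <- rbind(rank_of[ok], nb_rank[ok])
  }
  ev <- if (length(edges)) as.vector(do.call(cbind, edges)) else integer()
  g <- igraph::make_empty_graph(n = length(inm), directed = FALSE)
  if (length(ev)) g <- igraph::add_edges(g, ev)
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  first <- match(seq_along(sizes), memb)
  list(level = levels[inm][first], size = sizes,
       membership = memb, voxel_index = inm)
}

# Zone count matrix (ng x max zone size).
glszm_matrix <- function(levels, ng) {
  z <- label_zones(levels)
  smax <- max(z$size)
  idx <- (z$size - 1L) * ng + z$level
  matrix(tabulate(idx, nbins = ng * smax), ng, smax)
}

#' GLSZM features (16)
#'
#' Size-zone features over the 26-connected equal-level zones of the
#' discretized ROI. Zone percentage is the number of zones divided by the
#' number of in-mask voxels.
#'
#' @param droi A `discretized_roi`.
#' @return Named numeric vector of 16 features (prefix `glszm_`).
#' @export
glszm_features <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  lev <- crop_levels(droi)
  counts <- glszm_matrix(lev, droi$ng)
  nv <- sum(!is.na(lev))
  f <- ldm_common_features(counts)
  c(glszm_small_zone_emphasis = f$small,
    glszm_large_zone_emphasis = f$large,
    glszm_low_grey_level_zone_emphasis = f$low_gl,
    glszm_high_grey_level_zone_emphasis = f$high_gl,
    glszm_small_zone_low_grey_level_emphasis = f$small_low,
    glszm_small_zone_high_grey_level_emphasis = f$small_high,
    glszm_large_zone_low_grey_level_emphasis = f$large_low,
    glszm_large_zone_high_grey_level_emphasis = f$large_high,
    glszm_grey_level_non_uniformity = f$gln,
    glszm_grey_level_non_uniformity_normalised = f$glnn,
    glszm_zone_size_non_uniformity = f$sn,
    glszm_zone_size_non_uniformity_normalised = f$snn,
    glszm_zone_percentage = f$n / nv,
    glszm_grey_level_variance = f$gl_var,
    glszm_zone_size_variance = f$size_var,
    glszm_zone_size_entropy = f$entropy)
}
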