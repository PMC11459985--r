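# Grey-level co-occurrence matrix (GLCM), 3D merged aggregation: voxel
# pairs at a fixed Chebyshev distance are pooled over all 13 unique
# directions (and both orientations) into a single symmetric matrix.

# Build the merged symmetric co-occurrence count matrix.
glcm_matrix <- function(levels, ng, distance = 1L,
                        directions = offsets_13()) {
  counts <- matrix(0, ng, ng)
  for (r in seq_len(nrow(directions))) {
    nb <- shift_array(levels, directions[r, ] * distance)
    ok <- !is.na(levels) & !is.na(nb)
    if (!any(ok)) next
    idx <- (levels[ok] - 1L) * ng + nb[ok]
    tab <- tabulate(idx, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  counts + t(counts)  # symmetrize: count both orientations of each pair
}

#' GLCM features (25)
#'
#' Computes the 25 IBSI co-occurrence features from a single symmetric
#' matrix merged over all supplied directions at the given Chebyshev
#' distance. Probabilities are the normalized pair counts; entropies use
#' log base 2.
#'
#' @param droi A `discretized_roi` from [discretize_fbn()].
#' @param distance Pair distance in voxels (default 1).
#' @param directions Integer matrix of unique direction offsets (rows);
#'   default the 13 unique 3D directions.
#' @return Named numeric vector of 25 features (prefix `glcm_`).
#' @export
glcm_features <- function(droi, distance = 1L, directions = offsets_13()) {
  stopifnot(inherits(droi, "discretized_roi"))
  if (nrow(directions) == 0) stop("parameter error: no directions")
  lev <- crop_levels(droi)
  ng <- droi$ng
  counts <- glcm_matrix(lev, ng, distance, directions)
  if (sum(counts) == 0)
    stop("degenerate ROI: no valid voxel pairs for the GLCM")
  # drop empty grey levels outside the occupied range but keep level values
  p <- counts / sum(counts)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  pi_marg <- rowSums(p)

  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)

  # diagonal (|i-j|) and cross (i+j) probability distributions
  kd <- 0:(ng - 1)
  p_dif <- vapply(kd, function(k) sum(p[abs(i - j) == k]), 0)
  ks <- 2:(2 * ng)
  p_sum <- vapply(ks, function(k) sum(p[(i + j) == k]), 0)
  da <- sum(kd * p_dif)
  sa <- sum(ks * p_sum)

  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  hxy <- ent(p)
  pp <- outer(pi_marg, pi_marg)
  hxy1 <- -sum(p[pp > 0] * log2(pp[pp > 0]))
  hxy2 <- ent(pp)
  hx <- ent(pi_marg)

  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  off <- abs(i - j) != 0
  c(glcm_joint_maximum = max(p),
    glcm_joint_average = mu,
    glcm_joint_variance = sig2,
    glcm_joint_entropy = hxy,
    glcm_difference_average = da,
    glcm_difference_variance = sum((kd - da)^2 * p_dif),
    glcm_difference_entropy = ent(p_dif),
    glcm_sum_average = sa,
    glcm_sum_variance = sum((ks - sa)^2 * p_sum),
    glcm_sum_entropy = ent(p_sum),
    glcm_angular_second_moment = sum(p^2),
    glcm_contrast = sum((i - j)^2 * p),
    glcm_dissimilarity = sum(abs(i - j) * p),
    glcm_inverse_difference = sum(p / (1 + abs(i - j))),
    glcm_inverse_difference_normalised = sum(p / (1 + abs(i - j) / ng)),
    glcm_inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    glcm_inverse_difference_moment_normalised = sum(p / (1 + (i - j)^2 / ng^2)),
    glcm_inverse_variance = sum(p[off] / (i - j)[off]^2),
    glcm_correlation = corr,
    glcm_autocorrelation = sum(i * j * p),
    glcm_cluster_tendency = sum((i + j - 2 * mu)^2 * p),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * p),
    glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    glcm_information_correlation_1 = ic1,
    glcm_information_correlation_2 = ic2)
}
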