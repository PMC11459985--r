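# Grey-level run-length matrix (GLRLM), 3D merged aggregation: runs from
# all 13 unique directions are pooled into one matrix.

# Decompose the grid into maximal same-level runs along direction `d`.
# Returns a data.frame with columns level, length (one row per run).
runs_one_direction <- function(levels, d) {
  dm <- dim(levels)
  n <- length(levels)
  ijk <- arrayInd(seq_len(n), dm)
  # position along the line: the coordinate of the first nonzero axis of d,
  # sign-adjusted so it increases by 1 per step along the direction
  ax1 <- which(d != 0)[1]
  s <- ijk[, ax1] * d[ax1]
  # line anchor: constant along the line, unique per line
  kx <- ijk[, 1] - s * d[1]
  ky <- ijk[, 2] - s * d[2]
  kz <- ijk[, 3] - s * d[3]
  m <- max(dm) * 2L + 2L
  key <- (kx + m) + (ky + m) * (4L * m) + (kz + m) * (16L * m * m)
  ord <- order(key, s)
  lv <- levels[ord]
  ky2 <- key[ord]
  newrun <- c(TRUE, ky2[-1] != ky2[-n] |
                lv[-1] != lv[-n] |
                is.na(lv[-1]) != is.na(lv[-n]))
  newrun[is.na(newrun)] <- TRUE  # NA-valued comparisons mark breaks safely
  rid <- cumsum(newrun)
  keep <- !is.na(lv)
  if (!any(keep)) return(data.frame(level = integer(), length = integer()))
  lens <- tabulate(rid[keep], nbins = max(rid))
  run_ids <- which(lens > 0)
  first <- match(run_ids, rid)
  data.frame(level = lv[first], length = lens[run_ids])
}

# Merged run-length count matrix (ng x max run length) over all directions.
glrlm_matrix <- function(levels, ng, directions = offsets_13()) {
  runs <- do.call(rbind, lapply(seq_len(nrow(directions)), function(r) {
    runs_one_direction(levels, directions[r, ])
  }))
  lmax <- max(runs$length)
  idx <- (runs$length - 1L) * ng + runs$level
  matrix(tabulate(idx, nbins = ng * lmax), ng, lmax)
}

# Shared emphasis-style statistics for run/zone/distance matrices.
# counts: ng x m matrix indexed by (grey level, run length | zone size |
# zone distance). Returns the 14 statistics common to the three families
# plus the matrix total.
ldm_common_features <- function(counts) {
  ns <- sum(counts)
  ng <- nrow(counts)
  m <- ncol(counts)
  i <- matrix(seq_len(ng), ng, m)
  j <- matrix(seq_len(m), ng, m, byrow = TRUE)
  ri <- rowSums(counts)
  rj <- colSums(counts)
  p <- counts / ns
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  pe <- p[p > 0]
  list(
    n = ns,
    small = sum(counts / j^2) / ns,
    large = sum(counts * j^2) / ns,
    low_gl = sum(ri / seq_len(ng)^2) / ns,
    high_gl = sum(ri * seq_len(ng)^2) / ns,
    small_low = sum(counts / (i^2 * j^2)) / ns,
    small_high = sum(counts * i^2 / j^2) / ns,
    large_low = sum(counts * j^2 / i^2) / ns,
    large_high = sum(counts * i^2 * j^2) / ns,
    gln = sum(ri^2) / ns,
    glnn = sum(ri^2) / ns^2,
    sn = sum(rj^2) / ns,
    snn = sum(rj^2) / ns^2,
    gl_var = sum((i - mu_i)^2 * p),
    size_var = sum((j - mu_j)^2 * p),
    entropy = -sum(pe * log2(pe)))
}

#' GLRLM features (16)
#'
#' Run-length features from a single matrix merged over all supplied
#' directions. Run percentage is the number of runs divided by
#' `n_voxels * n_directions` (each voxel is covered once per direction).
#'
#' @param droi A `discretized_roi`.
#' @param directions Integer matrix of unique direction offsets.
#' @return Named numeric vector of 16 features (prefix `glrlm_`).
#' @export
glrlm_features <- function(droi, directions = offsets_13()) {
  stopifnot(inherits(droi, "discretized_roi"))
  lev <- crop_levels(droi)
  counts <- glrlm_matrix(lev, droi$ng, directions)
  nv <- sum(!is.na(lev))
  f <- ldm_common_features(counts)
  c(glrlm_short_runs_emphasis = f$small,
    glrlm_long_runs_emphasis = f$large,
    glrlm_low_grey_level_run_emphasis = f$low_gl,
    glrlm_high_grey_level_run_emphasis = f$high_gl,
    glrlm_short_run_low_grey_level_emphasis = f$small_low,
    glrlm_short_run_high_grey_level_emphasis = f$small_high,
    glrlm_long_run_low_grey_level_emphasis = f$large_low,
    glrlm_long_run_high_grey_level_emphasis = f$large_high,
    glrlm_grey_level_non_uniformity = f$gln,
    glrlm_grey_level_non_uniformity_normalised = f$glnn,
    glrlm_run_length_non_uniformity = f$sn,
    glrlm_run_length_non_uniformity_normalised = f$snn,
    glrlm_run_percentage = f$n / (nv * nrow(directions)),
    glrlm_grey_level_variance = f$gl_var,
    glrlm_run_length_variance = f$size_var,
    glrlm_run_entropy = f$entropy)
}
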