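# Voxelization of the phantom into activity volumes and ROI masks.

# Voxel-centre coordinates along one axis: n voxels symmetric about 0.
axis_coords <- function(extent, spacing) {
  n <- max(1L, floor(extent / spacing))
  (seq_len(n) - (n + 1) / 2) * spacing
}

grid_axes <- function(geom) {
  list(x = axis_coords(2 * geom$cylinder_radius, geom$voxel_spacing),
       y = axis_coords(2 * geom$cylinder_radius, geom$voxel_spacing),
       z = axis_coords(geom$cylinder_length, geom$voxel_spacing))
}

new_activity_volume <- function(data, spacing, origin) {
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "activity_volume")
}

new_roi_mask <- function(data, spacing, origin) {
  structure(list(data = data, spacing = spacing, origin = origin,
                 voxel_count = sum(data)),
            class = "roi_mask")
}

# Logical voxel-centre membership of one syringe cylinder.
# cx, cy: syringe axis position (mm); geometry supplies radius and length.
syringe_membership <- function(ax, cx, cy, geom) {
  inxy <- outer((ax$x - cx)^2, (ax$y - cy)^2, "+") <= geom$syringe_radius^2
  inz <- abs(ax$z) <= geom$syringe_length / 2
  outer(inxy, inz, "&")
}

# Absolute syringe centres (mm) for one insert position.
insert_syringe_centres <- function(geom, insert_index) {
  if (insert_index < 1 || insert_index > nrow(geom$insert_centers))
    stop("geometry error: insert_index out of range")
  off <- syringe_centres_2d(geom)
  cen <- geom$insert_centers[insert_index, ]
  cbind(off[, 1] + cen[1], off[, 2] + cen[2])
}

check_insert_overlap <- function(geom, insert_indices) {
  cen <- do.call(rbind, lapply(insert_indices, insert_syringe_centres,
                               geom = geom))
  d <- as.matrix(stats::dist(cen))
  diag(d) <- Inf
  if (any(d < 2 * geom$syringe_radius - 1e-9))
    stop("geometry error: syringes overlap")
  invisible(TRUE)
}

#' Voxelize one insert configuration into an activity volume
#'
#' Builds the full phantom grid with a single insert placed at the mounting
#' position `insert_index`. Voxels are assigned by the centre-point rule: a
#' voxel belongs to a syringe iff its centre lies inside the syringe
#' cylinder. Syringe voxels carry the syringe activity, necrotic syringes
#' and all other in-cylinder voxels carry the water background activity, and
#' voxels outside the cylinder are zero.
#'
#' @param geometry A [phantom_geometry()].
#' @param config An [insert_config()].
#' @param insert_index Mounting position (defaults to the config's shape id).
#' @return An `activity_volume`: list with `data` (3D array, kBq/ml),
#'   `spacing` (mm) and `origin` (mm coordinate of the centre of voxel
#'   `[1,1,1]`).
#' @seealso [build_phantom()] to place all four inserts in one volume.
#' @examples
#' vol <- build_activity_volume(phantom_geometry(), insert_config(1))
#' range(vol$data)
#' @export
build_activity_volume <- function(geometry, config,
                                  insert_index = config$shape_id) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(config, "insert_config"))
  build_phantom(geometry, list(config), insert_indices = insert_index)
}

#' Voxelize several inserts into one phantom volume
#'
#' Places each configuration in `configs` at the corresponding mounting
#' position (by default positions `1..length(configs)`), emulating a single
#' scan of the fully loaded phantom.
#'
#' @param geometry A [phantom_geometry()].
#' @param configs List of [insert_config()] objects.
#' @param insert_indices Mounting positions, one per config.
#' @return An `activity_volume`.
#' @export
build_phantom <- function(geometry, configs,
                          insert_indices = seq_along(configs)) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  if (length(configs) != length(insert_indices))
    stop("config error: one mounting position per insert config")
  if (length(configs) > nrow(geometry$insert_centers))
    stop("config error: more configs than mounting positions")
  for (cf in configs) {
    if (!inherits(cf, "insert_config")) stop("config error: not an insert_config")
    if (length(cf$syringe_activities) != geometry$syringes_per_insert)
      stop("config error: syringe count mismatch between config and geometry")
  }
  check_insert_overlap(geometry, insert_indices)

  ax <- grid_axes(geometry)
  nx <- length(ax$x); ny <- length(ax$y); nz <- length(ax$z)
  in_cyl_xy <- outer(ax$x^2, ax$y^2, "+") <= geometry$cylinder_radius^2
  vol <- array(0, dim = c(nx, ny, nz))
  vol[rep(in_cyl_xy, nz)] <- geometry$background_activity

  for (k in seq_along(configs)) {
    cen <- insert_syringe_centres(geometry, insert_indices[k])
    act <- configs[[k]]$syringe_activities
    for (s in seq_len(nrow(cen))) {
      if (is.na(act[s])) next  # necrotic: stays at background
      m <- syringe_membership(ax, cen[s, 1], cen[s, 2], geometry)
      vol[m] <- act[s]
    }
  }
  new_activity_volume(vol, spacing = geometry$voxel_spacing,
                      origin = c(ax$x[1], ax$y[1], ax$z[1]))
}

#' Ground-truth ROI mask for one insert position
#'
#' The region of interest is the union of the seven syringe cylinders of the
#' homogeneous (shape 1) insert footprint, translated to the requested
#' mounting position. The same mask geometry is reused for every insert
#' configuration and every reconstruction setting, removing delineation
#' variability from the analysis.
#'
#' @param geometry A [phantom_geometry()].
#' @param insert_index Mounting position of the insert to mask.
#' @return A `roi_mask`: list with logical `data` aligned to the phantom
#'   grid, `spacing`, `origin` and `voxel_count`.
#' @examples
#' m <- make_roi_mask(phantom_geometry(), 1)
#' m$voxel_count * phantom_geometry()$voxel_spacing^3 / 1000  # ~145 cm^3
#' @export
make_roi_mask <- function(geometry, insert_index) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  ax <- grid_axes(geometry)
  cen <- insert_syringe_centres(geometry, insert_index)
  m <- array(FALSE, dim = c(length(ax$x), length(ax$y), length(ax$z)))
  for (s in seq_len(nrow(cen)))
    m <- m | syringe_membership(ax, cen[s, 1], cen[s, 2], geometry)
  if (sum(m) < 2) stop("geometry error: ROI mask has fewer than 2 voxels")
  new_roi_mask(m, spacing = geometry$voxel_spacing,
               origin = c(ax$x[1], ax$y[1], ax$z[1]))
}

#' @export
print.activity_volume <- function(x, ...) {
  cat(sprintf("activity volume %s @ %g mm, range [%.3g, %.3g] kBq/ml\n",
              paste(dim(x$data), collapse = "x"), x$spacing,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask %s @ %g mm, %d voxels (%.1f cm^3)\n",
              paste(dim(x$data), collapse = "x"), x$spacing, x$voxel_count,
              x$voxel_count * x$spacing^3 / 1000))
  invisible(x)
}
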