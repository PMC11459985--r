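# Phantom geometry: a water cylinder holding four 7-syringe tumour inserts.

#' Define the cylindrical phantom geometry
#'
#' The digital phantom is a water-filled cylinder carrying low background
#' activity, with up to four artificial tumour inserts mounted at 90 degrees
#' to each other around the cylinder axis. Each insert is a bundle of seven
#' parallel syringes: one on the insert axis and six on a pitch circle of
#' diameter `pitch_circle_diameter`, so that neighbouring syringes just touch
#' when `syringe_radius` equals half the pitch-circle radius. The default
#' syringe dimensions (radius 9.5 mm, length 73 mm) give a total insert
#' volume of 7 * pi * 9.5^2 * 73 ~= 145 cm^3.
#'
#' All lengths are millimetres; activities are kBq/ml. The voxel grid is
#' isotropic with spacing `voxel_spacing`, centred on the cylinder axis.
#'
#' @param cylinder_radius Radius of the water cylinder (mm).
#' @param cylinder_length Axial length of the water cylinder (mm).
#' @param voxel_spacing Isotropic voxel spacing of the generated grid (mm).
#' @param syringe_radius Radius of one syringe (mm).
#' @param syringe_length Length of one syringe (mm).
#' @param pitch_circle_diameter Diameter of the circle on which the six outer
#'   syringes of an insert are mounted (mm).
#' @param background_activity Activity concentration of the water background
#'   (kBq/ml).
#' @param insert_offset Distance from the cylinder axis to each insert centre
#'   (mm).
#' @param n_inserts Number of insert mounting positions (equally spaced in
#'   angle).
#' @return An object of class `phantom_geometry`.
#' @examples
#' geom <- phantom_geometry()
#' geom$insert_centers
#' @export
phantom_geometry <- function(cylinder_radius = 100,
                             cylinder_length = 120,
                             voxel_spacing = 2,
                             syringe_radius = 9.5,
                             syringe_length = 73,
                             pitch_circle_diameter = 38,
                             background_activity = 5,
                             insert_offset = 55,
                             n_inserts = 4) {
  stopifnot(voxel_spacing > 0, cylinder_radius > 0, cylinder_length > 0,
            syringe_radius > 0, syringe_length > 0,
            pitch_circle_diameter > 0, background_activity >= 0,
            n_inserts >= 1)
  ang <- (seq_len(n_inserts) - 1) * 2 * pi / n_inserts
  centers <- cbind(x = insert_offset * cos(ang),
                   y = insert_offset * sin(ang),
                   z = rep(0, n_inserts))
  geom <- structure(list(
    cylinder_radius = cylinder_radius,
    cylinder_length = cylinder_length,
    voxel_spacing = voxel_spacing,
    syringe_radius = syringe_radius,
    syringe_length = syringe_length,
    pitch_circle_diameter = pitch_circle_diameter,
    background_activity = background_activity,
    insert_offset = insert_offset,
    insert_centers = centers,
    syringes_per_insert = 7L
  ), class = "phantom_geometry")
  validate_geometry(geom)
  geom
}

validate_geometry <- function(geom) {
  r_insert <- geom$pitch_circle_diameter / 2 + geom$syringe_radius
  if (geom$insert_offset + r_insert > geom$cylinder_radius)
    stop("geometry error: insert does not fit inside the cylinder radius")
  if (geom$syringe_length > geom$cylinder_length)
    stop("geometry error: syringes longer than the cylinder")
  # total insert volume must stay close to the 145 cm^3 tumour model
  vol <- 7 * pi * geom$syringe_radius^2 * geom$syringe_length / 1000 # cm^3
  if (abs(vol - 145) / 145 > 0.10)
    stop(sprintf(
      "geometry error: 7-syringe insert volume %.1f cm^3 outside 145 cm^3 +/- 10%%",
      vol))
  # syringes within one insert must not overlap (touching is allowed)
  cen <- syringe_centres_2d(geom)
  d <- as.matrix(stats::dist(cen))
  diag(d) <- Inf
  if (any(d < 2 * geom$syringe_radius - 1e-9))
    stop("geometry error: syringes overlap within an insert")
  invisible(geom)
}

# In-insert syringe centre offsets (mm), rows = 7 syringes:
# row 1 the central syringe, rows 2..7 the pitch-circle ring.
syringe_centres_2d <- function(geom) {
  rp <- geom$pitch_circle_diameter / 2
  ang <- (0:5) * pi / 3
  rbind(c(0, 0), cbind(rp * cos(ang), rp * sin(ang)))
}

#' Insert configurations: homogeneous and heterogeneous syringe fillings
#'
#' Four canonical insert configurations mirror the physical phantom:
#' * shape 1 — homogeneous: all 7 syringes at 40 kBq/ml;
#' * shape 2 — homogeneous with necrotic core: 6 syringes at 40 kBq/ml, the
#'   central syringe cold (`NA`, imaged as background water);
#' * shape 3 — heterogeneous: central syringe 40 kBq/ml, ring alternating
#'   80/20 kBq/ml (max/min ratio 4:1);
#' * shape 4 — heterogeneous with necrotic core: as shape 3 with the central
#'   syringe cold.
#'
#' `syringe_activities` may be supplied to override the canonical filling;
#' entry 1 is the central syringe, entries 2-7 the ring. `NA` marks a
#' necrotic (non-radioactive, water-filled) syringe.
#'
#' @param shape_id Integer 1-4 selecting the configuration.
#' @param syringe_activities Optional numeric vector of length 7 (kBq/ml,
#'   `NA` = necrotic) overriding the canonical filling for this shape.
#' @return An object of class `insert_config`.
#' @examples
#' insert_config(3)$syringe_activities
#' @export
insert_config <- function(shape_id, syringe_activities = NULL) {
  shape_id <- as.integer(shape_id)
  if (!shape_id %in% 1:4) stop("config error: shape_id must be 1, 2, 3 or 4")
  if (is.null(syringe_activities)) {
    syringe_activities <- switch(shape_id,
      rep(40, 7),
      c(NA, rep(40, 6)),
      c(40, 80, 20, 80, 20, 80, 20),
      c(NA, 80, 20, 80, 20, 80, 20))
  }
  if (length(syringe_activities) != 7L)
    stop("config error: syringe_activities must have 7 entries")
  act <- as.numeric(syringe_activities)
  hot <- act[!is.na(act)]
  if (any(hot < 0)) stop("config error: negative activity")
  n_necrotic <- sum(is.na(act))
  if (shape_id %in% c(1, 3) && n_necrotic != 0)
    stop("config error: shapes 1 and 3 have no necrotic syringe")
  if (shape_id %in% c(2, 4) && n_necrotic != 1)
    stop("config error: shapes 2 and 4 have exactly one necrotic syringe")
  if (shape_id %in% c(1, 2)) {
    if (length(unique(hot)) != 1)
      stop("config error: homogeneous shapes need a single activity level")
  } else {
    if (length(unique(hot)) < 2)
      stop("config error: heterogeneous shapes need >= 2 activity levels")
    if (abs(max(hot) / min(hot) - 4) > 1e-9)
      stop("config error: heterogeneous max/min activity ratio must be 4")
  }
  structure(list(shape_id = shape_id, syringe_activities = act),
            class = "insert_config")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  vol <- 7 * pi * x$syringe_radius^2 * x$syringe_length / 1000
  cat(sprintf(
    "phantom geometry: cylinder r=%g mm, L=%g mm, %g mm voxels\n",
    x$cylinder_radius, x$cylinder_length, x$voxel_spacing))
  cat(sprintf("  %d inserts, 7 syringes each (r=%g, L=%g mm, %.1f cm^3/insert)\n",
              nrow(x$insert_centers), x$syringe_radius, x$syringe_length, vol))
  invisible(x)
}

#' @export
print.insert_config <- function(x, ...) {
  lab <- ifelse(is.na(x$syringe_activities), "necrotic",
                paste0(x$syringe_activities, " kBq/ml"))
  cat(sprintf("insert config shape %d: [%s]\n", x$shape_id,
              paste(lab, collapse = ", ")))
  invisible(x)
}
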