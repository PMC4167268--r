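#' Uniformly spaced projection angles
#'
#' Angles for `n_angles` source positions spread uniformly over an arc,
#' with the endpoint excluded so that a full 360-degree scan does not
#' acquire 0 and 2*pi twice.
#'
#' @param n_angles number of projections (K >= 1).
#' @param arc angular span in radians (default full rotation, `2*pi`).
#' @param start first angle in radians.
#' @return numeric vector of length `n_angles`: `start + (0:(K-1)) * arc / K`.
#' @examples
#' make_uniform_angles(4)          # 0, pi/2, pi, 3*pi/2
#' @export
make_uniform_angles <- function(n_angles, arc = 2 * pi, start = 0) {
  n_angles <- check_count(n_angles, "n_angles")
  if (!is.finite(arc) || arc <= 0) stopf("'arc' must be positive")
  start + (seq_len(n_angles) - 1) * (arc / n_angles)
}

#' Circular-orbit cone-beam scan geometry
#'
#' Describes a point source on a circular orbit of radius `dso` about the
#' z axis with a flat detector, perpendicular to the orbit plane, rigidly
#' attached at source-to-detector distance `dsd`.
#'
#' @section Coordinate convention:
#' The world origin is the orbit center; the rotation axis is z.  At view
#' angle `theta` the source sits at `dso * (-sin(theta), cos(theta), 0)`
#' (on the +y axis at `theta = 0`) and looks through the origin along
#' `(sin(theta), -cos(theta), 0)`.  The detector u axis points along
#' `(cos(theta), sin(theta), 0)` and the v axis along +z.  Physical
#' detector coordinates (u, v) are measured from the central ray; this
#' choice fixes the left/right orientation of all images and is shared by
#' the forward projector and the backprojector.
#'
#' @param dso source-to-origin distance (orbit radius), > 0.
#' @param dsd source-to-detector distance, >= `dso`.
#' @param det_rows,det_cols detector grid size (rows index v, columns u).
#' @param det_spacing_u,det_spacing_v detector pixel pitch (length/pixel).
#' @param det_offset_u,det_offset_v offset of the detector center from the
#'   central ray, in physical length units.
#' @param angles projection angles in radians; if `NULL`, built from
#'   `n_angles`, `arc`, `start` via [make_uniform_angles()].
#' @param n_angles,arc,start uniform-angle parameters used when `angles`
#'   is `NULL`.
#' @return an object of class `cone_geometry`.
#' @examples
#' g <- cone_geometry(dso = 100, dsd = 150, det_rows = 60, det_cols = 64,
#'                    det_spacing_u = 2, det_spacing_v = 1.75, n_angles = 72)
#' g
#' @export
cone_geometry <- function(dso, dsd, det_rows, det_cols,
                          det_spacing_u = 1, det_spacing_v = 1,
                          det_offset_u = 0, det_offset_v = 0,
                          angles = NULL, n_angles = NULL,
                          arc = 2 * pi, start = 0) {
  dso <- check_positive(dso, "dso")
  dsd <- check_positive(dsd, "dsd")
  if (dsd < dso) stopf("'dsd' must be >= 'dso' (detector beyond the origin)")
  det_rows <- check_count(det_rows, "det_rows")
  det_cols <- check_count(det_cols, "det_cols")
  det_spacing_u <- check_positive(det_spacing_u, "det_spacing_u")
  det_spacing_v <- check_positive(det_spacing_v, "det_spacing_v")
  if (is.null(angles)) {
    if (is.null(n_angles)) stopf("give either 'angles' or 'n_angles'")
    angles <- make_uniform_angles(n_angles, arc, start)
  }
  angles <- as.numeric(angles)
  if (length(angles) < 1L || anyNA(angles)) stopf("'angles' must be non-empty and finite")
  structure(list(
    dso = dso, dsd = dsd, orbit_radius = dso,
    det_rows = det_rows, det_cols = det_cols,
    det_spacing_u = det_spacing_u, det_spacing_v = det_spacing_v,
    det_offset_u = as.numeric(det_offset_u),
    det_offset_v = as.numeric(det_offset_v),
    n_angles = length(angles), angles = angles
  ), class = "cone_geometry")
}

#' @export
print.cone_geometry <- function(x, ...) {
  cat("Cone-beam geometry (circular orbit)\n")
  cat(sprintf("  dso = %g, dsd = %g (magnification %.4g)\n",
              x$dso, x$dsd, x$dsd / x$dso))
  cat(sprintf("  detector: %d x %d px, pitch %g x %g, offset (%g, %g)\n",
              x$det_rows, x$det_cols, x$det_spacing_v, x$det_spacing_u,
              x$det_offset_u, x$det_offset_v))
  cat(sprintf("  %d views over [%.4g, %.4g] rad (arc ~ %.4g deg)\n",
              x$n_angles, min(x$angles), max(x$angles),
              geometry_arc(x) * 180 / pi))
  invisible(x)
}

## total angular arc implied by the angle list (uniform spacing assumed for
## the closing step; a single view counts as a full rotation's worth)
geometry_arc <- function(geom) {
  a <- geom$angles
  if (length(a) == 1L) return(2 * pi)
  d <- diff(a)
  mean(d) * length(a)
}

## TRUE when angle spacing is uniform to tol and the arc closes a full circle
is_full_scan <- function(geom, tol = 1e-6) {
  a <- geom$angles
  if (length(a) == 1L) return(FALSE)
  d <- diff(a)
  uniform <- max(abs(d - mean(d))) <= 1e-12 * max(1, abs(mean(d)))
  uniform && abs(mean(d) * length(a) - 2 * pi) < tol
}

#' Source position at a view angle
#'
#' @param geom a [cone_geometry()].
#' @param angle view angle in radians.
#' @return length-3 numeric vector, the world position of the X-ray source.
#' @export
source_position <- function(geom, angle) {
  geom$dso * c(-sin(angle), cos(angle), 0)
}

#' Detector axes and center at a view angle
#'
#' Returns the orthonormal detector frame at one view: the unit u axis
#' (transverse, in the orbit plane), the unit v axis (+z), the central-ray
#' direction, and the world position of the detector point hit by the
#' central ray.
#'
#' @inheritParams source_position
#' @return list with `u_axis`, `v_axis`, `ray`, `center` (3-vectors).
#' @export
detector_frame <- function(geom, angle) {
  ray <- c(sin(angle), -cos(angle), 0)
  list(u_axis = c(cos(angle), sin(angle), 0),
       v_axis = c(0, 0, 1),
       ray = ray,
       center = source_position(geom, angle) + geom$dsd * ray)
}

#' Map world points to detector coordinates and distance weight
#'
#' Central geometric step of cone-beam backprojection: for a world point
#' (x, y, z) and view angle theta, computes the physical detector
#' coordinates where the ray from the source through the point hits the
#' detector, and the distance weight that compensates beam divergence.
#' With `s = -x*sin(theta) + y*cos(theta)` (depth toward the source) and
#' `t = x*cos(theta) + y*sin(theta)` (transverse), the mapping is
#' `u = dsd * t / (dso - s)`, `v = dsd * z / (dso - s)`, and the weight is
#' `w2 = dso^2 / (dso - s)^2`.
#'
#' Coordinates are relative to the central ray; detector center offsets are
#' applied when converting to pixel indices.  Points at or behind the
#' source (`dso - s <= 0`) are flagged invalid and must be skipped.
#'
#' @param geom a [cone_geometry()].
#' @param x,y,z world coordinates, vectorized (recycled to common length).
#' @param angle single view angle in radians.
#' @return list with numeric vectors `u`, `v`, `w2` and logical `valid`.
#' @export
voxel_to_detector <- function(geom, x, y, z, angle) {
  sa <- sin(angle); ca <- cos(angle)
  s <- -x * sa + y * ca
  t <-  x * ca + y * sa
  den <- geom$dso - s
  valid <- den > 1e-12 * geom$dso
  u <- geom$dsd * t / den
  v <- geom$dsd * z / den
  w2 <- (geom$dso / den)^2
  list(u = u, v = v, w2 = w2, valid = valid)
}

## physical u coordinate of each detector column center (pixel-center
## alignment: index = (coord - offset)/spacing + (N-1)/2, 0-based)
det_u_coords <- function(geom) {
  (seq_len(geom$det_cols) - 1 - (geom$det_cols - 1) / 2) *
    geom$det_spacing_u + geom$det_offset_u
}

det_v_coords <- function(geom) {
  (seq_len(geom$det_rows) - 1 - (geom$det_rows - 1) / 2) *
    geom$det_spacing_v + geom$det_offset_v
}

#' Serialize a geometry to a plain list
#'
#' A flat key-value representation suitable for YAML/JSON config blocks;
#' angles are stored in degrees.  [as_cone_geometry()] inverts it and also
#' accepts `n_angles`/`arc_deg`/`start_deg` instead of an explicit list.
#'
#' @param geom a [cone_geometry()].
#' @return named list of plain scalars plus `angles_deg`.
#' @export
geometry_to_list <- function(geom) {
  list(dso = geom$dso, dsd = geom$dsd,
       det_rows = geom$det_rows, det_cols = geom$det_cols,
       det_spacing_u = geom$det_spacing_u, det_spacing_v = geom$det_spacing_v,
       det_offset_u = geom$det_offset_u, det_offset_v = geom$det_offset_v,
       angles_deg = geom$angles * 180 / pi)
}

#' @rdname geometry_to_list
#' @param x named list as produced by [geometry_to_list()] or read from a
#'   config file; instead of `angles_deg` it may carry `n_angles` with
#'   optional `arc_deg` and `start_deg`.
#' @export
as_cone_geometry <- function(x) {
  if (inherits(x, "cone_geometry")) return(x)
  if (!is.list(x)) stopf("cannot interpret object of class '%s' as a geometry",
                         class(x)[1])
  angles <- NULL
  if (!is.null(x$angles_deg)) angles <- as.numeric(x$angles_deg) * pi / 180
  cone_geometry(dso = x$dso, dsd = x$dsd,
                det_rows = x$det_rows, det_cols = x$det_cols,
                det_spacing_u = x$det_spacing_u %||% 1,
                det_spacing_v = x$det_spacing_v %||% 1,
                det_offset_u = x$det_offset_u %||% 0,
                det_offset_v = x$det_offset_v %||% 0,
                angles = angles,
                n_angles = x$n_angles,
                arc = (x$arc_deg %||% 360) * pi / 180,
                start = (x$start_deg %||% 0) * pi / 180)
}
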