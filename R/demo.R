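#' Bundled phantom-experiment configuration
#'
#' The canonical small test configuration: a 64 x 60 pixel detector, 72
#' projections over a full rotation, reconstructed onto a 64 x 60 x 50
#' voxel grid.  Source-to-origin distance is 100 and source-to-detector
#' 150 (magnification 1.5) in world units of one voxel pitch; detector
#' pixel pitch is 2.0 (u) x 1.75 (v), chosen so the bundled head phantom
#' ([demo_phantom()], a [shepp_logan_3d()] scaled to half-width 27) stays
#' inside the detector field of view at every angle.
#'
#' @return `demo_geometry()` a [cone_geometry()]; `demo_grid()` a
#'   [volume_grid()]; `demo_phantom()` an [ellipsoid_phantom()].
#' @export
demo_geometry <- function() {
  cone_geometry(dso = 100, dsd = 150, det_rows = 60, det_cols = 64,
                det_spacing_u = 2.0, det_spacing_v = 1.75, n_angles = 72)
}

#' @rdname demo_geometry
#' @export
demo_grid <- function() volume_grid(64, 60, 50, 1, 1, 1)

#' @rdname demo_geometry
#' @export
demo_phantom <- function() shepp_logan_3d(scale = 27)
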