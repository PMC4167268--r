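#' Reconstruction configuration
#'
#' Bundles the tunable choices of one FDK pipeline run.
#'
#' @param filter a [filter_spec()].
#' @param precision arithmetic precision of the run, `"double"` or
#'   `"single"` (single emulated by rounding to float32 after each
#'   pipeline stage and each accumulated view).
#' @param interp detector interpolation: `"bilinear"` or `"nearest"`.
#' @return an object of class `recon_config`.
#' @export
recon_config <- function(filter = filter_spec(),
                         precision = c("double", "single"),
                         interp = c("bilinear", "nearest")) {
  structure(list(filter = filter,
                 precision = match.arg(precision),
                 interp = match.arg(interp)),
            class = "recon_config")
}

## bilinear / nearest sampling of detector image q at fractional 0-based
## indices (iv rows, iu cols); samples outside the detector contribute 0
interp_detector <- function(q, iu, iv, interp = "bilinear") {
  nr <- nrow(q); nc <- ncol(q)
  val <- numeric(length(iu))
  if (interp == "nearest") {
    r <- round(iv); cc <- round(iu)
    ok <- r >= 0 & r <= nr - 1 & cc >= 0 & cc <= nc - 1
    val[ok] <- q[r[ok] + 1 + cc[ok] * nr]
  } else {
    # zero-padded border handles partially-covered edge cells
    qp <- matrix(0, nr + 2L, nc + 2L)
    qp[2:(nr + 1), 2:(nc + 1)] <- q
    ok <- iu > -1 & iu < nc & iv > -1 & iv < nr
    pr <- iv[ok] + 2; pc <- iu[ok] + 2
    r0 <- floor(pr); c0 <- floor(pc)
    fr <- pr - r0; fc <- pc - c0
    nrp <- nr + 2L
    i00 <- r0 + (c0 - 1) * nrp
    val[ok] <- (1 - fr) * (1 - fc) * qp[i00] +
               fr * (1 - fc) * qp[i00 + 1] +
               (1 - fr) * fc * qp[i00 + nrp] +
               fr * fc * qp[i00 + nrp + 1]
  }
  val
}

#' Backproject one filtered view into a volume
#'
#' Voxel-driven distance-weighted backprojection: every voxel center is
#' mapped through [voxel_to_detector()] to fractional detector indices,
#' the filtered view is interpolated there, multiplied by the distance
#' weight `w2 = dso^2/(dso - s)^2` and by `scale`, and accumulated into
#' the volume.  Voxels mapping outside the detector contribute zero;
#' voxels at or behind the source are skipped and counted.
#'
#' @param volume an [fdk_volume()] accumulator.
#' @param q filtered projection matrix (`det_rows` x `det_cols`).
#' @param geom a [cone_geometry()].
#' @param angle view angle in radians.
#' @param scale global per-view FDK scale; the pipeline uses
#'   `(arc/K)/2 * dsd/dso` (see [fdk_reconstruct()]).
#' @param interp `"bilinear"` or `"nearest"`.
#' @return the updated [fdk_volume()]; attribute `oob_fraction` gives the
#'   fraction of voxels mapping off the detector, `n_behind_source` the
#'   number of skipped voxels.
#' @export
backproject_view <- function(volume, q, geom, angle, scale = 1,
                             interp = "bilinear") {
  g <- volume$grid
  cs <- grid_coords(g)
  sa <- sin(angle); ca <- cos(angle)
  S2 <- outer(-cs$x * sa, cs$y * ca, "+")       # depth s, nx x ny
  T2 <- outer(cs$x * ca, cs$y * sa, "+")        # transverse t
  den <- geom$dso - S2
  valid <- as.vector(den > 1e-12 * geom$dso)
  u <- geom$dsd * T2 / den
  iu2 <- as.vector((u - geom$det_offset_u) / geom$det_spacing_u +
                     (geom$det_cols - 1) / 2)
  w2 <- as.vector((geom$dso / den)^2)
  nz <- g$nz; nxy <- length(iu2)
  iu <- rep(iu2, times = nz)
  V <- outer(as.vector(geom$dsd / den), cs$z)   # physical v, nxy x nz
  iv <- (as.vector(V) - geom$det_offset_v) / geom$det_spacing_v +
    (geom$det_rows - 1) / 2
  val <- interp_detector(q, iu, iv, interp)
  contrib <- val * rep(w2, times = nz) * scale
  bad <- !valid
  if (any(bad)) contrib[rep(bad, times = nz)] <- 0
  oob <- mean(!(iu > -1 & iu < geom$det_cols & iv > -1 & iv < geom$det_rows))
  volume$values <- volume$values + array(contrib, dim = c(g$nx, g$ny, nz))
  if (volume$precision == "single") volume$values <- round_f32(volume$values)
  attr(volume, "oob_fraction") <- oob
  attr(volume, "n_behind_source") <- sum(bad) * nz
  volume
}

#' FDK cone-beam reconstruction
#'
#' The full Feldkamp-Davis-Kress pipeline: cosine-weight each raw
#' projection, ramp-filter its detector rows, then accumulate the
#' distance-weighted backprojection of every view (in ascending view
#' order, so results are reproducible run to run).  Each view is scaled by
#' `(arc/K)/2 * dsd/dso`, which makes a reconstructed object recover its
#' absolute density for a full-circle scan.
#'
#' For arcs short of a full rotation a warning is issued: no short-scan
#' (redundancy) weighting is applied, so values will be biased.
#'
#' @param stack a [projection_stack()] with `stage = "raw"` (or
#'   `"weighted"`).
#' @param grid a [volume_grid()] describing the output lattice.
#' @param config a [recon_config()].
#' @return an [fdk_volume()]; attribute `oob_fraction` holds the per-view
#'   mean fraction of voxels that mapped off the detector.
#' @export
fdk_reconstruct <- function(stack, grid, config = recon_config()) {
  if (!inherits(stack, "projection_stack")) stopf("'stack' must be a projection_stack")
  geom <- stack$geom
  if (geom$n_angles < 1L || length(stack$data) == 0L)
    stopf("empty projection stack")
  if (anyNA(stack$data)) {
    bad <- which(apply(stack$data, 3, anyNA))
    stopf("NaN/NA values in projection view(s): %s",
          paste(bad, collapse = ", "))
  }
  if (stack$stage == "filtered")
    stopf("'stack' is already filtered; fdk_reconstruct expects raw or weighted data")
  arc <- geometry_arc(geom)
  if (arc < 2 * pi - 1e-6)
    warning(sprintf(paste("scan arc is %.4g deg < 360 deg and no short-scan",
                          "(Parker) weighting is applied; reconstructed values",
                          "will be biased"), arc * 180 / pi), call. = FALSE)
  single <- config$precision == "single"
  data <- stack$data
  if (single) data <- round_f32(data)
  scale <- (arc / geom$n_angles) / 2 * geom$dsd / geom$dso
  vol <- fdk_volume(0, grid, precision = config$precision)
  oob <- numeric(geom$n_angles)
  for (n in seq_len(geom$n_angles)) {
    q <- filter_projection(data[, , n], geom, config$filter,
                           weighted = stack$stage == "weighted")
    if (single) q <- round_f32(q)
    vol <- backproject_view(vol, q, geom, geom$angles[n], scale,
                            interp = config$interp)
    oob[n] <- attr(vol, "oob_fraction")
  }
  attr(vol, "oob_fraction") <- mean(oob)
  vol
}

#' Compare two volumes
#'
#' Elementwise difference between two volumes on identical grids, with the
#' summary scalars used to compare reconstructions (e.g. single- vs
#' double-precision runs).
#'
#' @param a,b [fdk_volume()] objects on the same grid.
#' @return list with `max_abs_diff`, `rmse`, and `diff` (an
#'   [fdk_volume()] holding `a - b`).
#' @export
compare_volumes <- function(a, b) {
  if (!inherits(a, "fdk_volume") || !inherits(b, "fdk_volume"))
    stopf("both arguments must be fdk_volume objects")
  if (!grids_equal(a$grid, b$grid))
    stopf("volume grids differ; cannot compare")
  d <- a$values - b$values
  list(max_abs_diff = max(abs(d)),
       rmse = sqrt(mean(d^2)),
       diff = fdk_volume(d, a$grid))
}
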