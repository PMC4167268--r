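#' Reconstruction volume lattice
#'
#' The target voxel grid: counts, spacings, and the world coordinate of the
#' center of voxel (0, 0, 0).  By default the grid is centered on the
#' world origin (the orbit center).
#'
#' @param nx,ny,nz voxel counts along x, y, z (>= 1).
#' @param dx,dy,dz voxel spacings (> 0).
#' @param origin length-3 world coordinate of the first voxel center;
#'   `NULL` centers the grid on the origin.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(nx, ny, nz, dx = 1, dy = 1, dz = 1, origin = NULL) {
  nx <- check_count(nx, "nx"); ny <- check_count(ny, "ny"); nz <- check_count(nz, "nz")
  dx <- check_positive(dx, "dx"); dy <- check_positive(dy, "dy"); dz <- check_positive(dz, "dz")
  if (is.null(origin))
    origin <- -c((nx - 1) * dx, (ny - 1) * dy, (nz - 1) * dz) / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L || anyNA(origin)) stopf("'origin' must be a finite 3-vector")
  structure(list(nx = nx, ny = ny, nz = nz, dx = dx, dy = dy, dz = dz,
                 origin = origin), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("Volume grid: %d x %d x %d voxels, spacing (%g, %g, %g), origin (%g, %g, %g)\n",
              x$nx, x$ny, x$nz, x$dx, x$dy, x$dz,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

## world coordinates of voxel centers along each axis
grid_coords <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$nx) - 1) * grid$dx,
       y = grid$origin[2] + (seq_len(grid$ny) - 1) * grid$dy,
       z = grid$origin[3] + (seq_len(grid$nz) - 1) * grid$dz)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$nx == b$nx && a$ny == b$ny && a$nz == b$nz &&
    max(abs(c(a$dx - b$dx, a$dy - b$dy, a$dz - b$dz,
              a$origin - b$origin))) <= tol
}

#' Volume of voxel values on a grid
#'
#' @param values 3D numeric array with dim `(nx, ny, nz)`; a scalar is
#'   recycled to a constant volume.
#' @param grid a [volume_grid()].
#' @param precision `"double"` or `"single"`; single-precision volumes
#'   hold doubles rounded to float32 (see [round_f32()]).
#' @return an object of class `fdk_volume` with fields `values`, `grid`,
#'   `precision`.
#' @export
fdk_volume <- function(values, grid, precision = c("double", "single")) {
  precision <- match.arg(precision)
  if (length(values) == 1L)
    values <- array(as.numeric(values), dim = c(grid$nx, grid$ny, grid$nz))
  if (!identical(dim(values), c(grid$nx, grid$ny, grid$nz)))
    stopf("values dim (%s) does not match grid (%d, %d, %d)",
          paste(dim(values), collapse = ", "), grid$nx, grid$ny, grid$nz)
  if (precision == "single") values <- round_f32(values)
  structure(list(values = values, grid = grid, precision = precision),
            class = "fdk_volume")
}

#' @export
print.fdk_volume <- function(x, ...) {
  cat(sprintf("FDK volume: %d x %d x %d voxels (%s precision)\n",
              x$grid$nx, x$grid$ny, x$grid$nz, x$precision))
  cat(sprintf("  value range [%.6g, %.6g], mean %.6g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
summary.fdk_volume <- function(object, ...) {
  v <- object$values
  out <- list(dim = dim(v), precision = object$precision,
              min = min(v), max = max(v), mean = mean(v),
              rms = sqrt(mean(v^2)))
  class(out) <- "summary.fdk_volume"
  out
}

#' @export
print.summary.fdk_volume <- function(x, ...) {
  cat(sprintf("FDK volume %d x %d x %d (%s): min %.6g, max %.6g, mean %.6g, rms %.6g\n",
              x$dim[1], x$dim[2], x$dim[3], x$precision,
              x$min, x$max, x$mean, x$rms))
  invisible(x)
}

#' Display an axial slice of a volume
#'
#' @param x an [fdk_volume()].
#' @param k axial (z) slice index; defaults to the central slice.
#' @param ... passed to [graphics::image()].
#' @export
plot.fdk_volume <- function(x, k = NULL, ...) {
  k <- k %||% ((x$grid$nz + 1L) %/% 2L)
  cs <- grid_coords(x$grid)
  graphics::image(cs$x, cs$y, x$values[, , k], asp = 1,
                  xlab = "x", ylab = "y",
                  main = sprintf("axial slice z = %.3g", cs$z[k]),
                  col = grDevices::gray.colors(256, 0, 1), ...)
  invisible(x)
}

#' Projection stack
#'
#' The ordered set of K detector images acquired (or simulated, or
#' filtered) at the geometry's view angles.  Data are stored as a 3D array
#' with dim `(det_rows, det_cols, n_angles)`; `data[, , n]` is view n.
#'
#' @param data 3D numeric array `(det_rows, det_cols, n_angles)`.
#' @param geom a [cone_geometry()].
#' @param stage processing stage: `"raw"`, `"weighted"` or `"filtered"`.
#' @param precision `"double"` or `"single"`.
#' @return an object of class `projection_stack`.
#' @export
projection_stack <- function(data, geom,
                             stage = c("raw", "weighted", "filtered"),
                             precision = c("double", "single")) {
  stage <- match.arg(stage)
  precision <- match.arg(precision)
  if (!inherits(geom, "cone_geometry")) stopf("'geom' must be a cone_geometry")
  if (!identical(dim(data), c(geom$det_rows, geom$det_cols, geom$n_angles)))
    stopf("data dim (%s) does not match geometry (%d, %d, %d)",
          paste(dim(data), collapse = ", "),
          geom$det_rows, geom$det_cols, geom$n_angles)
  if (precision == "single") data <- round_f32(data)
  structure(list(data = data, geom = geom, stage = stage,
                 precision = precision), class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  cat(sprintf("Projection stack: %d views of %d x %d px (%s, %s precision)\n",
              x$geom$n_angles, x$geom$det_rows, x$geom$det_cols,
              x$stage, x$precision))
  cat(sprintf("  value range [%.6g, %.6g]\n", min(x$data), max(x$data)))
  invisible(x)
}

## stage transitions only move forward: raw -> weighted -> filtered
check_stage_transition <- function(from, to) {
  order <- c(raw = 1L, weighted = 2L, filtered = 3L)
  if (order[[to]] <= order[[from]])
    stopf("invalid stage transition %s -> %s", from, to)
  invisible(TRUE)
}
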