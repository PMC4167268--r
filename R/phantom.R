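#' Ellipsoid phantom
#'
#' A synthetic object made of additive ellipsoids: the density at a point
#' is the sum of the densities of all ellipsoids containing it, so nested
#' structures are built with negative densities.  Each ellipsoid may be
#' rotated about the z axis.
#'
#' @param centers numeric matrix (n x 3) of ellipsoid centers, or a
#'   data.frame with columns `cx, cy, cz, a, b, c, phi_deg, density`
#'   (in which case the other arguments are ignored).
#' @param semi_axes numeric matrix (n x 3) of strictly positive semi-axes
#'   (a, b, c) along the ellipsoid's own x, y, z axes.
#' @param z_rot_deg rotation of each ellipsoid about z, degrees.
#' @param density additive density of each ellipsoid (may be negative).
#' @return an object of class `ellipsoid_phantom` (a data.frame with the
#'   columns above).
#' @seealso [shepp_logan_3d()] for the bundled head-like default.
#' @export
ellipsoid_phantom <- function(centers, semi_axes = NULL, z_rot_deg = 0,
                              density = 1) {
  if (is.data.frame(centers)) {
    df <- centers
    need <- c("cx", "cy", "cz", "a", "b", "c", "phi_deg", "density")
    if (!all(need %in% names(df)))
      stopf("phantom table must have columns: %s", paste(need, collapse = " "))
    df <- df[need]
  } else {
    centers <- rbind(centers)
    semi_axes <- rbind(semi_axes)
    n <- nrow(centers)
    if (ncol(centers) != 3L || ncol(semi_axes) != 3L || nrow(semi_axes) != n)
      stopf("'centers' and 'semi_axes' must be n x 3")
    df <- data.frame(cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
                     a = semi_axes[, 1], b = semi_axes[, 2], c = semi_axes[, 3],
                     phi_deg = rep_len(z_rot_deg, n),
                     density = rep_len(density, n))
  }
  if (nrow(df) > 0 && any(df$a <= 0 | df$b <= 0 | df$c <= 0))
    stopf("all semi-axes must be strictly positive")
  structure(df, class = c("ellipsoid_phantom", "data.frame"))
}

#' Empty phantom (zero density everywhere)
#' @return an `ellipsoid_phantom` with no ellipsoids.
#' @export
empty_phantom <- function() {
  ellipsoid_phantom(data.frame(cx = numeric(), cy = numeric(), cz = numeric(),
                               a = numeric(), b = numeric(), c = numeric(),
                               phi_deg = numeric(), density = numeric()))
}

#' Three-dimensional Shepp-Logan-style head phantom
#'
#' A ten-ellipsoid head-like phantom in the tradition of the Shepp-Logan
#' test object, with densities in a modified (unit-scale) range so that
#' absolute reconstruction errors are easy to interpret.  Coordinates are
#' defined inside the unit sphere and multiplied by `scale`.  This object
#' is a stand-in test fixture, not a replica of any particular scanner or
#' toolbox phantom.
#'
#' @param scale half-width of the phantom's bounding box in world units.
#' @return an [ellipsoid_phantom()].
#' @export
shepp_logan_3d <- function(scale = 1) {
  tab <- data.frame(
    cx = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    cy = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
    cz = c(0, 0, 0, 0, -0.15, 0.25, 0.25, 0, 0, 0),
    a = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    c = c(0.81, 0.78, 0.22, 0.28, 0.41, 0.05, 0.05, 0.05, 0.02, 0.02),
    phi_deg = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0),
    density = c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  )
  tab[c("cx", "cy", "cz", "a", "b", "c")] <-
    tab[c("cx", "cy", "cz", "a", "b", "c")] * scale
  ellipsoid_phantom(tab)
}

#' @export
print.ellipsoid_phantom <- function(x, ...) {
  cat(sprintf("Ellipsoid phantom: %d ellipsoid(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Read / write a phantom as a plain-text table
#'
#' One ellipsoid per row, whitespace-separated columns
#' `cx cy cz a b c phi_deg density`; lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_phantom()` returns an [ellipsoid_phantom()];
#'   `write_phantom()` returns `path` invisibly.
#' @export
read_phantom <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  ellipsoid_phantom(df)
}

#' @rdname read_phantom
#' @param phantom an [ellipsoid_phantom()].
#' @export
write_phantom <- function(phantom, path) {
  utils::write.table(as.data.frame(phantom), path, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

## density of the phantom at vectorized world points
phantom_density <- function(phantom, x, y, z) {
  out <- numeric(length(x))
  for (i in seq_len(nrow(phantom))) {
    e <- phantom[i, ]
    phi <- e$phi_deg * pi / 180
    dx <- x - e$cx; dy <- y - e$cy; dz <- z - e$cz
    xr <- cos(phi) * dx + sin(phi) * dy
    yr <- -sin(phi) * dx + cos(phi) * dy
    inside <- (xr / e$a)^2 + (yr / e$b)^2 + (dz / e$c)^2 <= 1
    out <- out + e$density * inside
  }
  out
}

#' Chord length of a ray through one ellipsoid
#'
#' Length of the intersection of a ray (full line) with an ellipsoid, or 0
#' if the ray misses it.  The ray is mapped into the frame in which the
#' ellipsoid is the unit sphere and the resulting quadratic is solved in
#' closed form.
#'
#' @param ellipsoid one-row phantom table (or a list) with fields
#'   `cx, cy, cz, a, b, c, phi_deg`.
#' @param ray_origin length-3 origin of the ray.
#' @param ray_dir length-3 direction, unit norm to 1e-12.
#' @return chord length (non-negative scalar).
#' @export
ray_ellipsoid_chord <- function(ellipsoid, ray_origin, ray_dir) {
  nrm <- sqrt(sum(ray_dir^2))
  if (nrm == 0) stopf("'ray_dir' must be non-zero")
  if (abs(nrm - 1) > 1e-12) stopf("'ray_dir' must be normalized (|d| = 1)")
  chord_lengths(ellipsoid, rbind(ray_origin), rbind(ray_dir))
}

## vectorized chord computation: origins, dirs are n x 3 (dirs unit)
chord_lengths <- function(e, origins, dirs) {
  phi <- e$phi_deg * pi / 180
  cp <- cos(phi); sp <- sin(phi)
  ox <- origins[, 1] - e$cx; oy <- origins[, 2] - e$cy; oz <- origins[, 3] - e$cz
  # rotate into ellipsoid frame, then scale axes to the unit sphere
  oxr <- (cp * ox + sp * oy) / e$a
  oyr <- (-sp * ox + cp * oy) / e$b
  ozr <- oz / e$c
  dxr <- (cp * dirs[, 1] + sp * dirs[, 2]) / e$a
  dyr <- (-sp * dirs[, 1] + cp * dirs[, 2]) / e$b
  dzr <- dirs[, 3] / e$c
  A <- dxr^2 + dyr^2 + dzr^2
  B <- 2 * (oxr * dxr + oyr * dyr + ozr * dzr)
  C <- oxr^2 + oyr^2 + ozr^2 - 1
  disc <- B^2 - 4 * A * C
  out <- numeric(nrow(origins))
  hit <- disc > 0
  out[hit] <- sqrt(disc[hit]) / A[hit]   # |lambda2 - lambda1|, dirs unit
  out
}

#' Analytic cone-beam forward projection of a phantom
#'
#' Exact line integrals: for each view and detector pixel, casts the ray
#' from the source through the pixel center and sums `density * chord`
#' over all ellipsoids.  Deterministic; one ray per pixel (pixel-center
#' sampling, no detector-footprint integration).
#'
#' @param phantom an [ellipsoid_phantom()].
#' @param geom a [cone_geometry()].
#' @return a [projection_stack()] with `stage = "raw"`.
#' @export
project_phantom <- function(phantom, geom) {
  if (!inherits(geom, "cone_geometry")) stopf("'geom' must be a cone_geometry")
  nr <- geom$det_rows; nc <- geom$det_cols; K <- geom$n_angles
  uu <- det_u_coords(geom)
  vv <- det_v_coords(geom)
  U <- matrix(rep(uu, each = nr), nr, nc)  # physical u per pixel
  V <- matrix(rep(vv, times = nc), nr, nc)
  data <- array(0, dim = c(nr, nc, K))
  for (n in seq_len(K)) {
    th <- geom$angles[n]
    fr <- detector_frame(geom, th)
    S <- source_position(geom, th)
    # world position of each pixel center
    px <- fr$center[1] + as.vector(U) * fr$u_axis[1]
    py <- fr$center[2] + as.vector(U) * fr$u_axis[2]
    pz <- fr$center[3] + as.vector(V)
    dx <- px - S[1]; dy <- py - S[2]; dz <- pz - S[3]
    nrm <- sqrt(dx^2 + dy^2 + dz^2)
    dirs <- cbind(dx / nrm, dy / nrm, dz / nrm)
    origins <- cbind(rep(S[1], nr * nc), S[2], S[3])
    acc <- numeric(nr * nc)
    for (i in seq_len(nrow(phantom)))
      acc <- acc + phantom$density[i] * chord_lengths(phantom[i, ], origins, dirs)
    data[, , n] <- acc
  }
  projection_stack(data, geom, stage = "raw")
}

#' Voxelize a phantom onto a grid
#'
#' Ground-truth volume for reconstruction-error metrics: each voxel value
#' is the mean phantom density over `supersample^3` sub-points placed on a
#' regular lattice inside the voxel.
#'
#' @param phantom an [ellipsoid_phantom()].
#' @param grid a [volume_grid()].
#' @param supersample sub-samples per axis per voxel (>= 1).
#' @return an [fdk_volume()].
#' @export
voxelize_phantom <- function(phantom, grid, supersample = 1) {
  supersample <- check_count(supersample, "supersample")
  cs <- grid_coords(grid)
  off <- ((seq_len(supersample) - 0.5) / supersample - 0.5)
  acc <- array(0, dim = c(grid$nx, grid$ny, grid$nz))
  X <- array(rep(cs$x, times = grid$ny * grid$nz), dim = dim(acc))
  Y <- array(rep(rep(cs$y, each = grid$nx), times = grid$nz), dim = dim(acc))
  Z <- array(rep(cs$z, each = grid$nx * grid$ny), dim = dim(acc))
  for (ox in off) for (oy in off) for (oz in off) {
    acc <- acc + phantom_density(phantom,
                                 X + ox * grid$dx,
                                 Y + oy * grid$dy,
                                 Z + oz * grid$dz)
  }
  fdk_volume(acc / supersample^3, grid)
}

#' Add Gaussian noise to a projection stack
#'
#' Adds i.i.d. Gaussian perturbations with standard deviation `noise_sd`
#' to every detector value; reproducible for a fixed seed.  The caller's
#' RNG state is preserved.  `noise_sd = 0` returns an identical copy.
#'
#' @param stack a [projection_stack()].
#' @param noise_sd standard deviation of the noise (>= 0).
#' @param seed integer seed.
#' @return a [projection_stack()] at the same stage/precision.
#' @export
add_noise <- function(stack, noise_sd, seed = 1L) {
  if (length(noise_sd) != 1L || !is.finite(noise_sd) || noise_sd < 0)
    stopf("'noise_sd' must be a single non-negative number")
  if (noise_sd == 0) return(stack)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  noisy <- stack$data + array(stats::rnorm(length(stack$data), sd = noise_sd),
                              dim = dim(stack$data))
  projection_stack(noisy, stack$geom, stage = stack$stage,
                   precision = stack$precision)
}
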