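## Independent reference implementations used as oracles.  These are kept
## deliberately literal (scalar loops, hand-assembled matrices) and share no
## code with the package internals they check.

## --- projective-matrix oracle -------------------------------------------
## 3x4 cone-beam projection matrix assembled from the documented frame:
## source at dso*(-sin t, cos t, 0), u axis (cos t, sin t, 0), v axis +z,
## central ray (sin t, -cos t, 0).
oracle_project_point <- function(geom, p, theta) {
  S <- geom$dso * c(-sin(theta), cos(theta), 0)
  ray <- c(sin(theta), -cos(theta), 0)
  uax <- c(cos(theta), sin(theta), 0)
  vax <- c(0, 0, 1)
  M <- rbind(c(geom$dsd * uax, -geom$dsd * sum(uax * S)),
             c(geom$dsd * vax, -geom$dsd * sum(vax * S)),
             c(ray, -sum(ray * S)))
  h <- as.vector(M %*% c(p, 1))
  list(u = h[1] / h[3], v = h[2] / h[3], w2 = (geom$dso / h[3])^2)
}

## --- scalar triple-loop backprojection ----------------------------------
## Literal voxel loop with its own scalar bilinear interpolation.
oracle_backproject <- function(values, grid, q, geom, theta, scale,
                               interp = "bilinear") {
  xs <- grid$origin[1] + (seq_len(grid$nx) - 1) * grid$dx
  ys <- grid$origin[2] + (seq_len(grid$ny) - 1) * grid$dy
  zs <- grid$origin[3] + (seq_len(grid$nz) - 1) * grid$dz
  nr <- nrow(q); nc <- ncol(q)
  sample_q <- function(iu, iv) {
    if (interp == "nearest") {
      r <- round(iv); cc <- round(iu)
      if (r < 0 || r > nr - 1 || cc < 0 || cc > nc - 1) return(0)
      return(q[r + 1, cc + 1])
    }
    c0 <- floor(iu); r0 <- floor(iv)
    fu <- iu - c0; fv <- iv - r0
    g <- function(r, cc) {
      if (r < 0 || r > nr - 1 || cc < 0 || cc > nc - 1) 0 else q[r + 1, cc + 1]
    }
    (1 - fv) * (1 - fu) * g(r0, c0) + (1 - fv) * fu * g(r0, c0 + 1) +
      fv * (1 - fu) * g(r0 + 1, c0) + fv * fu * g(r0 + 1, c0 + 1)
  }
  for (i in seq_len(grid$nx)) for (j in seq_len(grid$ny)) {
    s <- -xs[i] * sin(theta) + ys[j] * cos(theta)
    t <- xs[i] * cos(theta) + ys[j] * sin(theta)
    den <- geom$dso - s
    if (den <= 0) next
    u <- geom$dsd * t / den
    iu <- (u - geom$det_offset_u) / geom$det_spacing_u + (nc - 1) / 2
    w2 <- (geom$dso / den)^2
    for (k in seq_len(grid$nz)) {
      v <- geom$dsd * zs[k] / den
      iv <- (v - geom$det_offset_v) / geom$det_spacing_v + (nr - 1) / 2
      values[i, j, k] <- values[i, j, k] + scale * w2 * sample_q(iu, iv)
    }
  }
  values
}

## --- direct circular convolution of one padded row ----------------------
oracle_filter_row <- function(row, H) {
  pad <- length(H)
  h <- Re(stats::fft(H, inverse = TRUE)) / pad
  x <- c(row, rep(0, pad - length(row)))
  y <- numeric(pad)
  idx <- seq_len(pad) - 1
  for (j in seq_len(pad))
    y[j] <- sum(x * h[((j - 1 - idx) %% pad) + 1])
  y[seq_along(row)]
}

## --- trapezoid quadrature of the inside-indicator along a ray -----------
oracle_chord_quadrature <- function(ellipsoid, origin, dir, rel_step = 1e-4) {
  e <- as.list(ellipsoid)
  R <- max(e$a, e$b, e$c)
  # bracket the ellipsoid: distance from origin to center +/- a margin
  d0 <- sum((c(e$cx, e$cy, e$cz) - origin) * dir)
  lam <- seq(d0 - 2 * R, d0 + 2 * R, by = rel_step * R)
  phi <- e$phi_deg * pi / 180
  px <- origin[1] + lam * dir[1] - e$cx
  py <- origin[2] + lam * dir[2] - e$cy
  pz <- origin[3] + lam * dir[3] - e$cz
  xr <- (cos(phi) * px + sin(phi) * py) / e$a
  yr <- (-sin(phi) * px + cos(phi) * py) / e$b
  zr <- pz / e$c
  f <- as.numeric(xr^2 + yr^2 + zr^2 <= 1)
  h <- rel_step * R
  sum((f[-1] + f[-length(f)]) / 2) * h
}

## --- 2D parallel-beam filtered backprojection reference -----------------
## Disks (circles in the z = 0 plane), analytic parallel sinogram, ramp
## filter by frequency sampling, pixel-driven backprojection.  Ray at view
## angle t and detector coordinate s runs along (sin t, -cos t); a point
## (x, y) has detector coordinate x*cos t + y*sin t.
oracle_parallel_fbp <- function(disks, angles, t_coords, dt, xs, ys) {
  nt <- length(t_coords)
  pad <- 1L
  while (pad < 2 * nt) pad <- pad * 2L
  k <- 0:(pad - 1); k <- ifelse(k > pad / 2, k - pad, k)
  H <- abs(k) / (pad * dt)
  img <- matrix(0, length(xs), length(ys))
  dth <- diff(angles[1:2])
  for (th in angles) {
    sino <- numeric(nt)
    for (d in seq_len(nrow(disks))) {
      cproj <- disks$cx[d] * cos(th) + disks$cy[d] * sin(th)
      off2 <- (t_coords - cproj)^2
      inside <- off2 < disks$r[d]^2
      sino[inside] <- sino[inside] +
        disks$rho[d] * 2 * sqrt(disks$r[d]^2 - off2[inside])
    }
    xp <- c(sino, rep(0, pad - nt))
    q <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE))[seq_len(nt)] / pad
    tp <- outer(xs * cos(th), ys * sin(th), "+")
    fi <- (tp - t_coords[1]) / dt
    i0 <- pmin(pmax(floor(fi), 0), nt - 2)
    fr <- pmin(pmax(fi - i0, 0), 1)
    img <- img + (dth / 2) * ((1 - fr) * q[i0 + 1] + fr * q[i0 + 2])
  }
  img
}

## small helper fixtures ---------------------------------------------------
tiny_geometry <- function(n_angles = 8, det_rows = 16, det_cols = 16,
                          spacing = 2, dso = 100, dsd = 150) {
  cone_geometry(dso = dso, dsd = dsd, det_rows = det_rows,
                det_cols = det_cols, det_spacing_u = spacing,
                det_spacing_v = spacing, n_angles = n_angles)
}

max_rel_diff <- function(a, b) {
  scale <- max(abs(b), 1e-300)
  max(abs(a - b)) / scale
}
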