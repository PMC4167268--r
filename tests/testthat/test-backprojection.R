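test_that("backprojecting a zero view leaves the volume unchanged", {
  g <- tiny_geometry()
  grid <- volume_grid(8, 8, 4)
  vol <- fdk_volume(0, grid)
  out <- backproject_view(vol, matrix(0, 16, 16), g, 0.4, scale = 1)
  expect_true(all(out$values == 0))
})

test_that("a single hot detector pixel increments only voxels near its ray", {
  g <- tiny_geometry()
  grid <- volume_grid(16, 16, 16, 2, 2, 2)
  q <- matrix(0, 16, 16)
  q[9, 5] <- 1
  th <- 0.9
  vol <- backproject_view(fdk_volume(0, grid), q, g, th, scale = 1)
  hit <- which(vol$values != 0, arr.ind = TRUE)
  expect_gt(nrow(hit), 0)
  cs <- grid_coords(grid)
  for (r in seq_len(nrow(hit))) {
    m <- voxel_to_detector(g, cs$x[hit[r, 1]], cs$y[hit[r, 2]],
                           cs$z[hit[r, 3]], th)
    iu <- (m$u - g$det_offset_u) / g$det_spacing_u + (g$det_cols - 1) / 2
    iv <- (m$v - g$det_offset_v) / g$det_spacing_v + (g$det_rows - 1) / 2
    # within one interpolation cell of the hot pixel's (0-based) index (8, 4)
    expect_lt(abs(iu - 4), 1)
    expect_lt(abs(iv - 8), 1)
  }
})

test_that("vectorized backprojection equals the scalar triple-loop reference", {
  set.seed(51)
  for (interp in c("bilinear", "nearest")) {
    g <- cone_geometry(dso = 90, dsd = 140, det_rows = 8, det_cols = 8,
                       det_spacing_u = 6, det_spacing_v = 6,
                       det_offset_u = 1.3, det_offset_v = -0.8, n_angles = 5)
    grid <- volume_grid(5, 5, 3, 6, 5, 7, origin = c(-12, -11, -6))
    q <- matrix(stats::rnorm(64), 8, 8)
    th <- 2.2
    got <- backproject_view(fdk_volume(0, grid), q, g, th, scale = 0.37,
                            interp = interp)$values
    ref <- oracle_backproject(array(0, c(5, 5, 3)), grid, q, g, th, 0.37,
                              interp = interp)
    expect_lt(max_rel_diff(got, ref), 1e-6)
  }
})

test_that("larger grids still match the reference exactly enough", {
  set.seed(52)
  g <- tiny_geometry(n_angles = 3)
  grid <- volume_grid(16, 16, 16, 3, 3, 3)
  q <- matrix(stats::rnorm(256), 16, 16)
  got <- backproject_view(fdk_volume(0, grid), q, g, g$angles[2], scale = 1)$values
  ref <- oracle_backproject(array(0, c(16, 16, 16)), grid, q, g, g$angles[2], 1)
  expect_lt(max_rel_diff(got, ref), 1e-5)
})

test_that("the full pipeline matches a literal reference pipeline", {
  # 16 x 16 detector, 36 views, 12^3 grid: weight by the closed-form map,
  # filter every row by direct convolution, backproject with the scalar loop
  g <- cone_geometry(dso = 100, dsd = 150, det_rows = 16, det_cols = 16,
                     det_spacing_u = 4, det_spacing_v = 4, n_angles = 36)
  ph <- ellipsoid_phantom(rbind(c(0, 0, 0), c(6, -4, 3)),
                          rbind(c(15, 12, 10), c(5, 4, 6)),
                          c(0, 25), c(1, 0.5))
  st <- project_phantom(ph, g)
  grid <- volume_grid(12, 12, 12, 3, 3, 3)
  pad <- 64L
  got <- fdk_reconstruct(st, grid,
                         recon_config(filter = filter_spec("ramp", 1, pad)))$values

  H <- ramp_kernel(filter_spec("ramp", 1, pad), g$det_spacing_u)
  # closed-form weight map from physical coordinates (rows index v)
  uu <- ((1:16) - 1 - 7.5) * 4
  vv <- ((1:16) - 1 - 7.5) * 4
  wmap <- g$dsd / sqrt(g$dsd^2 + outer(vv^2, uu^2, "+"))
  scale <- (2 * pi / 36) / 2 * g$dsd / g$dso
  ref <- array(0, c(12, 12, 12))
  for (n in 1:36) {
    pw <- st$data[, , n] * wmap
    qn <- t(apply(pw, 1, oracle_filter_row, H = H))
    ref <- oracle_backproject(ref, grid, qn, g, g$angles[n], scale)
  }
  expect_lt(max_rel_diff(got, ref), 1e-5)
})

test_that("reconstruction rejects degenerate stacks and reports shapes", {
  g <- tiny_geometry(n_angles = 2)
  bad <- projection_stack(array(0, c(16, 16, 2)), g)
  bad$data[3, 3, 2] <- NaN
  expect_error(fdk_reconstruct(bad, volume_grid(4, 4, 4)), "view.*2")
  st <- projection_stack(array(0, c(16, 16, 2)), g)
  vol <- fdk_reconstruct(st, volume_grid(4, 5, 6))
  expect_equal(dim(vol$values), c(4, 5, 6))
  expect_true(all(vol$values == 0))
})

test_that("the pipeline is linear in the projection data", {
  g <- tiny_geometry(n_angles = 8)
  ph <- ellipsoid_phantom(c(0, 0, 0), c(10, 8, 6), 10, 1)
  st <- project_phantom(ph, g)
  grid <- volume_grid(10, 10, 8, 3, 3, 3)
  v1 <- fdk_reconstruct(st, grid)$values
  st3 <- projection_stack(3 * st$data, g)
  v3 <- fdk_reconstruct(st3, grid)$values
  expect_equal(v3, 3 * v1, tolerance = 1e-12)
})

test_that("cyclically shifting the stack equals rotating the reconstruction", {
  # quarter-turn version: on a square, centered grid a 90-degree rotation is
  # an exact array operation, so the equality holds to float reassociation
  g <- cone_geometry(dso = 100, dsd = 150, det_rows = 16, det_cols = 16,
                     det_spacing_u = 3, det_spacing_v = 3, n_angles = 8)
  ph <- ellipsoid_phantom(rbind(c(6, 2, 1), c(-5, -7, -2)),
                          rbind(c(7, 5, 6), c(4, 6, 5)), c(30, -10), c(1, 0.6))
  st <- project_phantom(ph, g)
  grid <- volume_grid(14, 14, 6, 1, 1, 1)
  v <- fdk_reconstruct(st, grid)$values
  # phantom rotated by +90 deg <=> each view comes from 2 steps earlier
  shifted <- st$data[, , c(7, 8, 1:6)]
  v_shift <- fdk_reconstruct(projection_stack(shifted, g), grid)$values
  rot <- aperm(v[, 14:1, , drop = FALSE], c(2, 1, 3))
  expect_lt(max(abs(v_shift - rot)), 1e-8 * max(abs(v)))
})

test_that("short-scan arcs reconstruct only with a loud warning", {
  g <- cone_geometry(dso = 100, dsd = 150, det_rows = 8, det_cols = 8,
                     det_spacing_u = 6, det_spacing_v = 6,
                     n_angles = 6, arc = pi)
  st <- projection_stack(array(1, c(8, 8, 6)), g)
  expect_warning(fdk_reconstruct(st, volume_grid(4, 4, 2)), "Parker")
})

test_that("volume comparison reports exact differences and rejects grid mismatch", {
  grid <- volume_grid(4, 4, 4)
  a <- fdk_volume(array(stats::runif(64), c(4, 4, 4)), grid)
  expect_equal(compare_volumes(a, a)$max_abs_diff, 0)
  b <- fdk_volume(a$values + 0.5, grid)
  cmp <- compare_volumes(b, a)
  expect_equal(cmp$max_abs_diff, 0.5)
  expect_equal(cmp$rmse, 0.5)
  expect_equal(cmp$diff$values, array(0.5, c(4, 4, 4)))
  c_ <- fdk_volume(array(0, c(5, 4, 4)), volume_grid(5, 4, 4))
  expect_error(compare_volumes(a, c_), "grids differ")
})
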