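test_that("ray-ellipsoid chord matches closed forms on spheres", {
  sphere <- ellipsoid_phantom(c(0, 0, 0), c(7, 7, 7), 0, 1)
  # through the center: the diameter, from any direction
  for (d in list(c(1, 0, 0), c(0, 0, 1), c(1, 1, 1) / sqrt(3))) {
    expect_equal(ray_ellipsoid_chord(sphere[1, ], c(-50, 0, 0) * 0 - 100 * d, d),
                 14, tolerance = 1e-12)
  }
  # impact parameter beyond the radius: a miss
  expect_equal(ray_ellipsoid_chord(sphere[1, ], c(-100, 7.01, 0), c(1, 0, 0)), 0)
  # known off-center chord: 2*sqrt(r^2 - b^2)
  expect_equal(ray_ellipsoid_chord(sphere[1, ], c(-100, 3, 0), c(1, 0, 0)),
               2 * sqrt(49 - 9), tolerance = 1e-12)
  expect_error(ray_ellipsoid_chord(sphere[1, ], c(0, 0, 0), c(0, 0, 0)), "non-zero")
  expect_error(ray_ellipsoid_chord(sphere[1, ], c(0, 0, 0), c(2, 0, 0)), "normalized")
})

test_that("chord lengths agree with trapezoid quadrature on random ellipsoids", {
  set.seed(31)
  worst <- 0
  for (rep in 1:12) {
    e <- ellipsoid_phantom(stats::runif(3, -5, 5),
                           stats::runif(3, 2, 10),
                           stats::runif(1, -90, 90), 1)[1, ]
    d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
    o <- as.numeric(c(e$cx, e$cy, e$cz)) + stats::runif(3, -3, 3) - 40 * d
    got <- ray_ellipsoid_chord(e, o, d)
    ref <- oracle_chord_quadrature(e, o, d)
    if (ref > 1) worst <- max(worst, abs(got - ref) / ref)
  }
  expect_lt(worst, 1e-3)
})

test_that("projection of an empty phantom is a zero stack of the right shape", {
  g <- tiny_geometry(n_angles = 5)
  st <- project_phantom(empty_phantom(), g)
  expect_equal(dim(st$data), c(16, 16, 5))
  expect_true(all(st$data == 0))
  expect_identical(st$stage, "raw")
})

test_that("a centered sphere projects its diameter through the central ray", {
  # odd detector so a pixel center sits exactly on the central ray
  g <- cone_geometry(dso = 100, dsd = 150, det_rows = 15, det_cols = 15,
                     det_spacing_u = 2, det_spacing_v = 2, n_angles = 9)
  st <- project_phantom(ellipsoid_phantom(c(0, 0, 0), c(9, 9, 9), 0, 1), g)
  expect_equal(as.numeric(st$data[8, 8, ]), rep(18, 9), tolerance = 1e-12)
})

test_that("projection is linear in the phantom and scales with density", {
  g <- tiny_geometry(n_angles = 4)
  a <- ellipsoid_phantom(c(3, -2, 1), c(8, 6, 5), 15, 0.7)
  b <- ellipsoid_phantom(c(-4, 5, -2), c(5, 9, 7), -30, 1.2)
  ab <- ellipsoid_phantom(rbind(c(3, -2, 1), c(-4, 5, -2)),
                          rbind(c(8, 6, 5), c(5, 9, 7)),
                          c(15, -30), c(0.7, 1.2))
  expect_identical(project_phantom(ab, g)$data,
                   project_phantom(a, g)$data + project_phantom(b, g)$data)
  a2 <- a; a2$density <- 2 * a$density
  expect_identical(project_phantom(a2, g)$data, 2 * project_phantom(a, g)$data)
})

test_that("point-reflected phantoms project to v-flipped opposing views", {
  # the u axis co-rotates, so at theta + pi the opposing projection of the
  # point-reflected object is the original flipped along v only
  g <- tiny_geometry(n_angles = 6, det_rows = 16, det_cols = 18)
  ph <- ellipsoid_phantom(rbind(c(5, -3, 4), c(-8, 2, -6)),
                          rbind(c(6, 9, 5), c(4, 3, 7)), c(20, -35), c(1, 0.7))
  ph_reflected <- ph
  ph_reflected[c("cx", "cy", "cz")] <- -ph[c("cx", "cy", "cz")]
  g_op <- cone_geometry(dso = g$dso, dsd = g$dsd, det_rows = 16, det_cols = 18,
                        det_spacing_u = 2, det_spacing_v = 2,
                        angles = g$angles + pi)
  s1 <- project_phantom(ph, g)
  s2 <- project_phantom(ph_reflected, g_op)
  expect_lt(max(abs(s1$data - s2$data[16:1, , ])), 1e-9)
})

test_that("voxelization reproduces trivial volumes and converges in mass", {
  grid <- volume_grid(16, 16, 16, 1, 1, 1)
  expect_true(all(voxelize_phantom(empty_phantom(), grid)$values == 0))
  # voxels fully inside a big sphere get exactly the density
  big <- ellipsoid_phantom(c(0, 0, 0), c(40, 40, 40), 0, 1)
  expect_true(all(voxelize_phantom(big, grid, supersample = 2)$values == 1))
  # total mass converges to (4/3) pi R^3 as supersampling increases
  R <- 6
  sph <- ellipsoid_phantom(c(0, 0, 0), c(R, R, R), 0, 1)
  true_mass <- 4 / 3 * pi * R^3
  err <- sapply(c(1, 3), function(ss) {
    v <- voxelize_phantom(sph, grid, supersample = ss)
    abs(sum(v$values) * grid$dx * grid$dy * grid$dz - true_mass)
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2] / true_mass, 0.01)
})

test_that("phantom tables round-trip through the text format", {
  ph <- shepp_logan_3d(scale = 25)
  path <- withr::local_tempfile(fileext = ".txt")
  write_phantom(ph, path)
  ph2 <- read_phantom(path)
  expect_equal(as.data.frame(ph2), as.data.frame(ph), tolerance = 1e-12)
})

test_that("noise injection is seeded, unbiased in spread, and optional", {
  g <- cone_geometry(dso = 100, dsd = 150, det_rows = 100, det_cols = 100,
                     det_spacing_u = 1, det_spacing_v = 1, n_angles = 10)
  st <- projection_stack(array(0, c(100, 100, 10)), g)
  expect_identical(add_noise(st, 0, seed = 5)$data, st$data)
  n1 <- add_noise(st, 0.1, seed = 7)
  n2 <- add_noise(st, 0.1, seed = 7)
  n3 <- add_noise(st, 0.1, seed = 8)
  expect_identical(n1$data, n2$data)
  expect_false(identical(n1$data, n3$data))
  expect_lt(abs(stats::sd(n1$data) - 0.1) / 0.1, 0.03)
  expect_error(add_noise(st, -0.1), "non-negative")
  # the caller's RNG stream is untouched
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(add_noise(st, 0.1, seed = 3)); after <- stats::runif(1)
  expect_identical(before, after)
})
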