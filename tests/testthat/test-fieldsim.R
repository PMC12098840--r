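test_that("loop field reproduces on-axis closed forms", {
  lp <- loop_spec(radius = 0.05, current = 1)
  f0 <- loop_field(lp, 0, 0)
  expect_equal(f0$B_z, MU0 * 1 / (2 * 0.05), tolerance = 1e-12)
  expect_identical(f0$B_r, 0)
  fz <- loop_field(lp, 0, 0.05)
  expect_equal(fz$B_z, MU0 / (2 * 0.05) * 2^(-1.5), tolerance = 1e-12)
})

test_that("loop field matches Biot-Savart quadrature off axis", {
  lp <- loop_spec(radius = 0.05, current = 1)
  f <- loop_field(lp, 0.02, 0.01)
  o <- quad_loop_field(0.05, 1, 0.02, 0.01)
  expect_equal(f$B_r, o[["B_r"]], tolerance = 1e-6)
  expect_equal(f$B_z, o[["B_z"]], tolerance = 1e-6)
})

test_that("evaluation on the filament itself is rejected as singular", {
  lp <- loop_spec(radius = 0.05, current = 1)
  expect_error(loop_field(lp, 0.05, 0), "singular")
  expect_error(loop_field(lp, -0.01, 0), "non-negative")
})

test_that("thick-coil centre field matches the closed form", {
  cl <- microscopy_coil()
  map <- coil_field(cl, data.frame(r = 0, z = 0))
  expected <- thick_coil_center_field(0.0175, 0.0675, 0.04, 2000, 2.2)
  # filament discretisation converges to the exact uniform-density value
  expect_equal(map$B_mT, expected * 1e3, tolerance = 1e-4)
})

test_that("fields are exactly linear in the drive current", {
  pts <- field_grid(r = c(0, 0.005, 0.01), z = c(-0.01, 0, 0.01))
  m1 <- coil_field(microscopy_coil(current = 2.2), pts)
  m2 <- coil_field(microscopy_coil(current = 4.4), pts)
  expect_identical(m2$B_mT, 2 * m1$B_mT)
  a1 <- array_field(arena10_array(current = 6), pts)
  a3 <- array_field(arena10_array(current = 18), pts)
  expect_equal(a3$B_mT, 3 * a1$B_mT, tolerance = 1e-15)
})

test_that("on-axis radial field vanishes for axisymmetric configurations", {
  pts <- field_grid(r = 0, z = seq(-0.1, 0.1, by = 0.02))
  m <- array_field(arena10_array(), pts)
  expect_true(all(abs(m$B_r) < 1e-12 * abs(m$B_z)))
})

test_that("a Helmholtz pair reproduces the textbook centre field", {
  pair <- coil_array(
    coil_spec(0.1 - 5e-7, 1e-6, 1e-6, turns = 1, current = 1,
              axial_center = -0.05),
    coil_spec(0.1 - 5e-7, 1e-6, 1e-6, turns = 1, current = 1,
              axial_center = 0.05))
  m <- array_field(pair, data.frame(r = 0, z = 0), n_r = 1, n_z = 1)
  expect_equal(m$B_z, (4 / 5)^1.5 * MU0 / 0.1, tolerance = 1e-5)
})

test_that("symmetric arrays are mirror-symmetric about the mid-plane", {
  arr <- arena20_array()
  z <- c(0.013, 0.041, 0.087)
  up <- array_field(arr, field_grid(r = c(0.01, 0.06), z = z))
  dn <- array_field(arr, field_grid(r = c(0.01, 0.06), z = -z))
  expect_equal(up$B_mT, dn$B_mT, tolerance = 1e-10)
})

test_that("array construction catches bad input", {
  expect_error(coil_array(), "at least one coil")
  expect_error(coil_field(microscopy_coil(), data.frame(r = 0, z = 0),
                          n_r = 0), "positive")
  expect_warning(coil_array(coil_spec(0.1, 0.01, 0.05, 10, 1, 0),
                            coil_spec(0.1, 0.01, 0.05, 10, 1, 0.01)),
                 "overlap")
})

test_that("square-loop centre field matches the closed form", {
  sq <- rect_coil_spec(1 - 1e-9, 1 - 1e-9, 1 + 1e-9, 1 + 1e-9,
                       length = 1e-9, turns = 1, current = 1)
  m <- rect_coil_field(sq, data.frame(x = 0, y = 0, z = 0),
                       n_build = 1, n_axial = 1)
  expect_equal(m$B_z, 2 * sqrt(2) * MU0 / pi, tolerance = 1e-6)
})

test_that("rectangular loop matches line-integral quadrature", {
  rc <- rect_coil_spec(0.095, 0.035, 0.095 + 2e-9, 0.035 + 2e-9,
                       length = 1e-9, turns = 1, current = 2)
  pts <- data.frame(x = c(0.01, -0.02), y = c(0.005, 0.008),
                    z = c(0.03, -0.05))
  m <- rect_coil_field(rc, pts, n_build = 1, n_axial = 1)
  verts <- rbind(c(0.0475, -0.0175, 0), c(0.0475, 0.0175, 0),
                 c(-0.0475, 0.0175, 0), c(-0.0475, -0.0175, 0))
  for (i in 1:2) {
    o <- quad_polyline_field(verts, 2, as.numeric(pts[i, ]), n = 20000)
    expect_equal(c(m$B_x[i], m$B_y[i], m$B_z[i]), o, tolerance = 1e-6)
  }
})

test_that("rectangular coil far field approaches the dipole limit", {
  a <- 0.02; b <- 0.01
  rc <- rect_coil_spec(a - 1e-9, b - 1e-9, a + 1e-9, b + 1e-9,
                       length = 1e-9, turns = 1, current = 1)
  zfar <- 1.0  # 50x the loop size
  m <- rect_coil_field(rc, data.frame(x = 0, y = 0, z = zfar),
                       n_build = 1, n_axial = 1)
  mdip <- 1 * a * b              # m = I * A
  Bdip <- MU0 * 2 * mdip / (4 * pi * zfar^3)
  expect_equal(m$B_z, Bdip, tolerance = 0.01)
})

test_that("points on a rectangular winding segment are rejected", {
  rc <- rect_coil_spec(0.1 - 1e-9, 0.1 - 1e-9, 0.1 + 1e-9, 0.1 + 1e-9,
                       length = 1e-9, turns = 1, current = 1)
  expect_error(rect_coil_field(rc, data.frame(x = 0.05, y = 0, z = 0),
                               n_build = 1, n_axial = 1), "singular")
})

test_that("filament discretisation is converged at the default density", {
  cl <- microscopy_coil()
  pts <- field_grid(r = seq(0, 0.01, by = 0.002),
                    z = seq(-0.01, 0.01, by = 0.002))
  reg <- region_spec("cylinder", radius = 0.01, height = 0.02)
  h20 <- homogeneity(coil_field(cl, pts, 20, 20), reg)$homogeneity
  h40 <- homogeneity(coil_field(cl, pts, 40, 40), reg)$homogeneity
  expect_lt(abs(h20 - h40), 0.05)
})

test_that("resistance estimates follow the wire-table arithmetic", {
  cl <- coil_spec(1 / (2 * pi) - 0.0005, 0.001, 0.01, turns = 1, current = 1)
  expect_equal(estimate_resistance(cl, ohm_per_m = 1), 1, tolerance = 1e-12)
  cl2 <- coil_spec(0.0475, 0.005, 0.01, turns = 100, current = 1,
                   wire_gauge = 18)
  expect_equal(estimate_resistance(cl2), 100 * 2 * pi * 0.05 * 0.020948,
               tolerance = 1e-12)
  # the nominal-wire estimate for the microscopy coil: the as-built part
  # reads far lower, so this is an estimator, not a measurement
  expect_equal(estimate_resistance(microscopy_coil()),
               2000 * 2 * pi * 0.0425 * 0.020948, tolerance = 1e-12)
  cl3 <- coil_spec(0.05, 0.01, 0.01, turns = 10, current = 1, wire_gauge = 99)
  expect_error(estimate_resistance(cl3), "supported AWG gauges")
  expect_gt(estimate_inductance(microscopy_coil()), 0)
})
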