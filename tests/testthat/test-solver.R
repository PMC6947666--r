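test_that("equilibrium pitch recovers the undeformed pitch at d = d0", {
  m <- niti_material()
  for (g in bench_geometries()[c(1, 5, 10)]) {
    expect_equal(equilibrium_pitch(g, m, g$d0), g$p0, tolerance = 1e-9)
  }
})

test_that("equilibrium pitch matches grid-search minimization and grows under compression", {
  g <- in_vivo_geometry()
  m <- niti_material()
  p12 <- equilibrium_pitch(g, m, 12.0e-3)
  expect_gt(p12, g$p0)
  expect_equal(p12, grid_pitch_oracle(g, m, 12.0e-3), tolerance = 1e-6)
  # pitch strictly increases as diameter decreases over the design range
  ds <- seq(g$d0, 0.75 * g$d0, length.out = 25)
  ps <- vapply(ds, function(d) equilibrium_pitch(g, m, d), numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_error(equilibrium_pitch(g, m, 1.01 * g$d0), "exceeds")
  expect_error(equilibrium_pitch(g, m, 0), "positive")
})

test_that("stationarity quartic has zero p^2 term and vanishes at the energy minimum", {
  m_default <- niti_material()
  cases <- fixture_generator(seed = 42, n = 100)
  ratios <- rep(c(0.99, 0.95, 0.9, 0.8), length.out = length(cases))
  for (i in seq_along(cases)) {
    g <- cases[[i]]$geom
    mat <- cases[[i]]$mat
    a <- pitch_polynomial(g, mat, ratios[i] * g$d0)
    expect_identical(a[3], 0)
    p_star <- grid_pitch_oracle(g, mat, ratios[i] * g$d0)
    resid <- sum(a * p_star^(0:4)) / a[5]
    expect_lt(abs(resid), 1e-6)
  }
})

test_that("contact line force vanishes unloaded, scales with modulus, obeys virtual work", {
  g <- in_vivo_geometry()
  m <- niti_material()
  expect_equal(contact_line_force(g, m, g$d0), 0, tolerance = 1e-12)

  d <- 0.95 * g$d0
  # virtual-work oracle: f = (2/l) |dE_min/dd|, central difference
  expect_equal(contact_line_force(g, m, d),
               virtual_work_force_oracle(g, m, d), tolerance = 1e-3)

  # the closed form is linear in the section stiffnesses
  for (k in c(0.5, 2, 10)) {
    mk <- wire_material(E = k * m$E, nu = m$nu)
    expect_equal(contact_line_force(g, mk, d), k * contact_line_force(g, m, d),
                 tolerance = 1e-12)
  }
})

test_that("supported pressure is zero unloaded and increases monotonically under compression", {
  m <- niti_material()
  for (g in bench_geometries()) {
    expect_equal(pressure_for_diameter(g, m, g$d0), 0, tolerance = 1e-12)
    ds <- seq(0.7 * g$d0, g$d0, length.out = 100)
    rhos <- vapply(ds, function(d) pressure_for_diameter(g, m, d), numeric(1))
    expect_true(all(diff(rhos) < 0))
  }
})

test_that("pressure-diameter inversion is exact at zero and consistent with the forward map", {
  g <- in_vivo_geometry()
  m <- niti_material()
  st0 <- diameter_under_pressure(g, m, 0)
  expect_identical(st0$d, g$d0)
  expect_identical(st0$p, g$p0)
  expect_identical(st0$energy, 0)
  expect_equal(st0$area_ratio, 1)

  for (g in bench_geometries()) {
    st <- diameter_under_pressure(g, m, cmh2o(10))
    expect_lt(st$d, g$d0)
    expect_gt(st$p, g$p0)
    expect_gt(st$area_ratio, 0)
    expect_lt(st$area_ratio, 1)
    # forward map recovers the imposed pressure
    expect_equal(pressure_for_diameter(g, m, st$d), cmh2o(10),
                 tolerance = 1e-8)
  }
  expect_error(diameter_under_pressure(g, m, -1), "not modelled")
})

test_that("scaling modulus and pressure together leaves the deformation unchanged", {
  g <- in_vivo_geometry()
  m <- niti_material()
  m2 <- wire_material(E = 2 * m$E, nu = m$nu)
  d1 <- diameter_under_pressure(g, m, cmh2o(8))$d
  d2 <- diameter_under_pressure(g, m2, 2 * cmh2o(8))$d
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("pressure sweep starts at the identity state, is monotone and grid-consistent", {
  g <- in_vivo_geometry()
  m <- niti_material()
  sw11 <- pressure_sweep(g, m, cmh2o(10), n_points = 11)
  expect_equal(nrow(sw11), 11)
  expect_identical(sw11$area_ratio[1], 1)
  expect_true(all(diff(sw11$area_ratio) <= 0))

  # the refined sweep contains the coarse values at shared pressures
  sw101 <- pressure_sweep(g, m, cmh2o(10), n_points = 101)
  shared <- seq(1, 101, by = 10)
  expect_equal(sw101$pressure[shared], sw11$pressure, tolerance = 1e-12)
  expect_equal(sw101$d[shared], sw11$d, tolerance = 1e-9)
  expect_equal(sw101$p[shared], sw11$p, tolerance = 1e-9)
  expect_error(pressure_sweep(g, m, cmh2o(10), n_points = 1), "at least 2")
})

test_that("results are invariant to the unit system for consistent inputs", {
  # SI (m, Pa) vs (mm, MPa): dimensionless outputs must agree
  g_si <- helix_geometry(13.21e-3, 18.6e-3, 0.51e-3, 3)
  m_si <- wire_material(75e9, 0.3)
  g_mm <- helix_geometry(13.21, 18.6, 0.51, 3)
  m_mm <- wire_material(75e3, 0.3)  # MPa
  expect_equal(helix_angle(g_si$d0, g_si$p0), helix_angle(g_mm$d0, g_mm$p0),
               tolerance = 1e-12)
  rho_si <- cmh2o(10)
  st_si <- diameter_under_pressure(g_si, m_si, rho_si)
  st_mm <- diameter_under_pressure(g_mm, m_mm, rho_si * 1e-6, tol_d = 1e-10)
  expect_equal(st_si$area_ratio, st_mm$area_ratio, tolerance = 1e-12)
  expect_equal(helix_angle(st_si$d, st_si$p), helix_angle(st_mm$d, st_mm$p),
               tolerance = 1e-12)
})
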