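test_that("design table enumerates the wire x angle grid with template-based pitches", {
  m <- niti_material()
  tbl <- build_design_table(mat = m)
  expect_s3_class(tbl, "design_table")
  expect_equal(nrow(tbl), 10)
  # pitch grid: pi * 12.7 mm * tan(theta), shared by both wires
  expect_equal(round(tbl$p0[tbl$d_wire == 0.38e-3] * 1e3, 1),
               c(10.7, 14.5, 18.6, 23.0, 27.9))
  expect_equal(round(tbl$p0[tbl$d_wire == 0.51e-3] * 1e3, 1),
               c(10.7, 14.5, 18.6, 23.0, 27.9))
  # d0 = template + wire; outer = d0 + wire
  expect_equal(tbl$d0, tbl$d_wire + 12.7e-3)
  expect_equal(tbl$outer_d, tbl$d0 + tbl$d_wire)
  expect_true(all(tbl$area_ratio_at_ref > 0 & tbl$area_ratio_at_ref < 1))
  # thicker wire gives stiffer stent at every angle
  a38 <- tbl$area_ratio_at_ref[tbl$d_wire == 0.38e-3]
  a51 <- tbl$area_ratio_at_ref[tbl$d_wire == 0.51e-3]
  expect_true(all(a51 > a38))

  tbl0 <- build_design_table(rho_ref = 0, mat = m)
  expect_true(all(tbl0$area_ratio_at_ref == 1))

  tbl6 <- build_design_table(wire_diameters = c(0.3e-3, 0.4e-3, 0.5e-3),
                             thetas = c(20, 30), rho_ref = 0, mat = m)
  expect_equal(nrow(tbl6), 6)
  expect_error(build_design_table(wire_diameters = numeric(0), mat = m),
               "nonempty")
})

test_that("maximum-pitch criterion solves the target area reduction and stiffens with E", {
  m <- niti_material()
  p_max <- max_pitch_for_target_reduction(d_wire = 0.38e-3, mat = m,
                                          target_area_reduction = 0.30)
  # regression fixture (bisection at 0.01 mm pitch tolerance)
  expect_equal(p_max, 28.25e-3, tolerance = 1e-3)
  # the solved pitch indeed attains the target ratio
  g <- helix_geometry(12.7e-3 + 0.38e-3, p_max, 0.38e-3)
  expect_equal(diameter_under_pressure(g, m, cmh2o(10))$area_ratio, 0.70,
               tolerance = 2e-3)
  # a stiffer wire material needs a larger pitch to reach the same collapse
  p_max_stiff <- max_pitch_for_target_reduction(
    d_wire = 0.38e-3, mat = wire_material(E = 90e9, nu = 0.3),
    target_area_reduction = 0.30)
  expect_gt(p_max_stiff, p_max)
  expect_error(
    max_pitch_for_target_reduction(d_wire = 0.38e-3, mat = m,
                                   target_area_reduction = 0),
    "strictly in")
  # unattainable target within the bracket reports the failure
  expect_error(
    max_pitch_for_target_reduction(d_wire = 0.38e-3, mat = m,
                                   target_area_reduction = 0.5,
                                   bracket = pitch_from_angle(12.7e-3, c(5, 20))),
    "no solution")
})

test_that("wire-insensitivity criterion finds the largest pitch with matched collapse", {
  m <- niti_material()
  p_min <- wire_insensitive_pitch(d_wire_small = 0.38e-3,
                                  d_wire_large = 0.51e-3, mat = m)
  # regression fixture
  expect_equal(p_min, 10.11e-3, tolerance = 2e-3)
  # at the solution the two wires differ by exactly the tolerance
  ar <- function(dw, p) {
    g <- helix_geometry(12.7e-3 + dw, p, dw)
    diameter_under_pressure(g, m, cmh2o(10))$area_ratio
  }
  expect_equal(abs(ar(0.38e-3, p_min) - ar(0.51e-3, p_min)), 0.05,
               tolerance = 2e-3)
  # the difference shrinks monotonically as pitch decreases
  ps <- seq(6e-3, 26e-3, length.out = 6)
  diffs <- vapply(ps, function(p) abs(ar(0.38e-3, p) - ar(0.51e-3, p)),
                  numeric(1))
  expect_true(all(diff(diffs) > 0))
  # a tolerance that is always met returns the upper bracket edge
  br <- pitch_from_angle(12.7e-3, c(5, 40))
  expect_equal(wire_insensitive_pitch(d_wire_small = 0.38e-3,
                                      d_wire_large = 0.51e-3, mat = m,
                                      tol = 0.99, bracket = br), br[2])
  expect_error(wire_insensitive_pitch(d_wire_small = 0.51e-3,
                                      d_wire_large = 0.38e-3, mat = m),
               "smaller")
})

test_that("stent selection picks the smallest preloading diameter", {
  cand <- c(10.03, 11.62, 13.21, 14.80, 16.38) * 1e-3
  sel <- select_stent(cand, 13.2e-3)
  expect_equal(sel$selected, 13.21e-3)
  expect_equal(sel$margin, 0.01e-3, tolerance = 1e-9)
  # exact-fit boundary is inclusive
  expect_equal(select_stent(cand, 11.62e-3)$selected, 11.62e-3)
  # oversizing beyond the cap warns
  expect_warning(select_stent(cand, 14.9e-3, margin_cap = 1e-3), "oversized")
  expect_error(select_stent(cand, 17e-3), "no available")
})
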