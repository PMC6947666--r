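# Shared fixtures and independent oracles.
#
# The ten bench-study geometries: template 12.7 mm, two wire diameters,
# pitches equal to helix angles {15, 20, 25, 30, 35} deg on the template.
# SI units throughout.
bench_geometries <- function(n_coils = 3) {
  out <- list()
  for (dw in c(0.38e-3, 0.51e-3)) {
    for (p0 in c(10.7e-3, 14.5e-3, 18.6e-3, 23.0e-3, 27.9e-3)) {
      out[[length(out) + 1L]] <- helix_geometry(
        d0 = 12.7e-3 + dw, p0 = p0, d_wire = dw, n_coils = n_coils)
    }
  }
  out
}

niti_material <- function() wire_material(E = 75e9, nu = 0.3)

in_vivo_geometry <- function() {
  helix_geometry(d0 = 13.21e-3, p0 = 18.6e-3, d_wire = 0.51e-3, n_coils = 3)
}

# Dense-grid energy minimization oracle for the equilibrium pitch:
# scan the elastic energy on a <= 1 um pitch grid, then refine with
# stats::optimize on the bracketing interval. Independent of the quartic
# route: only the energy definition is shared.
grid_pitch_oracle <- function(geom, mat, d, p_hi = 2.5 * geom$p0) {
  ps <- seq(0.99 * geom$p0, p_hi, by = min(1e-6, geom$p0 / 5000))
  en <- elastic_energy(geom, mat, d, ps)
  i <- which.min(en)
  lo <- ps[max(1L, i - 1L)]
  hi <- ps[min(length(ps), i + 1L)]
  stats::optimize(function(p) elastic_energy(geom, mat, d, p),
                  c(lo, hi), tol = 1e-12)$minimum
}

# Virtual-work oracle for the radial line force: the energy stored at the
# constrained minimum, differentiated in diameter. Moving every point of
# the wire radially by delta_d / 2 against a line force f does work
# f * l * delta_d / 2, so f = (2 / l) |dE_min/dd|.
virtual_work_force_oracle <- function(geom, mat, d, h = 1e-7 * geom$d0) {
  e_min <- function(dd) {
    elastic_energy(geom, mat, dd, equilibrium_pitch(geom, mat, dd))
  }
  (2 / geom$l) * abs((e_min(d + h) - e_min(d - h)) / (2 * h))
}

cmh2o <- function(x) pressure_convert(x, "cmH2O", "Pa")
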