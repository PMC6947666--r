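#' Elastic energy of a deformed helix
#'
#' Change in elastic potential energy when the stent, constrained to remain
#' helical, moves from its stress-free shape `(d0, p0)` to `(d, p)`:
#' `E = (l / 2) (u - u_hat)' K (u - u_hat)` with `u = curvature_vector(d, p)`
#' and `K = diag(k_b, k_b, k_t)`. Because the rod is inextensible and
#' unshearable, bending and twisting of the centerline are the only energy
#' terms; `E >= 0` with equality iff `(d, p) = (d0, p0)`.
#'
#' @param geom a [helix_geometry()].
#' @param mat a [wire_material()].
#' @param d trial helix diameter (> 0).
#' @param p trial pitch (> 0).
#' @return energy (force x length units).
#' @export
elastic_energy <- function(geom, mat, d, p) {
  stopifnot(inherits(geom, "helix_geometry"), inherits(mat, "wire_material"))
  check_pos(d, "d")
  check_pos(p, "p")
  ks <- geom_stiffness(geom, mat)
  energy_dp(geom, ks, d, p)
}

# Hot path used by the solvers: stiffness precomputed, vectorized over p.
energy_dp <- function(geom, ks, d, p) {
  c2 <- pi^2 * d^2 + p^2
  dy <- 2 * pi^2 * d / c2 - geom$u_hat[2]
  dz <- 2 * pi * p / c2 - geom$u_hat[3]
  (geom$l / 2) * (ks$k_b * dy^2 + ks$k_t * dz^2)
}
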