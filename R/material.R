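#' Section stiffnesses of a solid round wire
#'
#' Bending stiffness `k_b = E I = E pi r^4 / 4` and torsional stiffness
#' `k_t = G J = G pi r^4 / 2` for a solid circular cross section of radius
#' `r = d_wire / 2`, with shear modulus `G = E / (2 (1 + nu))`. These are
#' the diagonal entries of the rod stiffness matrix `K = diag(k_b, k_b, k_t)`.
#' Note `k_t / k_b = 1 / (1 + nu)`, so `nu = 0` gives `k_t = k_b` exactly.
#'
#' @param E Young's modulus (pressure units, > 0).
#' @param nu Poisson ratio, in `[0, 0.5)`.
#' @param d_wire wire diameter (> 0).
#' @return named list with `k_b`, `k_t` (units pressure x length^4).
#' @examples
#' section_stiffness(75e9, 0.3, 0.51e-3)
#' @export
section_stiffness <- function(E, nu, d_wire) {
  check_material(E, nu)
  check_pos(d_wire, "d_wire")
  r4 <- (d_wire / 2)^4
  G <- E / (2 * (1 + nu))
  list(k_b = E * pi * r4 / 4, k_t = G * pi * r4 / 2)
}

#' Linear-elastic wire material
#'
#' Elastic constants of the stent wire. The NiTi wire used for airway
#' stents is superelastic; the deformation model assumes linear elasticity,
#' so a single effective modulus is used. Defaults are typical of austenitic
#' NiTi: `E = 75` GPa, `nu = 0.3` (SI units).
#'
#' If `d_wire` is supplied the section stiffnesses `k_b`, `k_t` and the
#' stiffness matrix `K` are derived and stored; the solver functions ignore
#' them and always derive stiffness from the geometry's own wire diameter,
#' so one `wire_material` can serve a whole design sweep.
#'
#' @param E Young's modulus (pressure units, > 0). Default 75e9 (Pa).
#' @param nu Poisson ratio in `[0, 0.5)`. Default 0.3.
#' @param d_wire optional wire diameter for deriving section stiffness.
#' @return an object of class `wire_material`.
#' @export
wire_material <- function(E = 75e9, nu = 0.3, d_wire = NULL) {
  check_material(E, nu)
  mat <- list(E = E, nu = nu, G = E / (2 * (1 + nu)), d_wire = d_wire)
  if (!is.null(d_wire)) {
    ks <- section_stiffness(E, nu, d_wire)
    mat$k_b <- ks$k_b
    mat$k_t <- ks$k_t
    mat$K <- diag(c(ks$k_b, ks$k_b, ks$k_t))
  }
  class(mat) <- "wire_material"
  mat
}

#' @export
print.wire_material <- function(x, ...) {
  cat("Wire material (linear elastic)\n")
  cat(sprintf("  E  : %g\n  nu : %g  (G = %g)\n", x$E, x$nu, x$G))
  if (!is.null(x$d_wire)) {
    cat(sprintf("  d_wire %g -> k_b = %g, k_t = %g\n", x$d_wire, x$k_b, x$k_t))
  }
  invisible(x)
}

check_material <- function(E, nu) {
  check_pos(E, "E")
  if (!is.numeric(nu) || any(!is.finite(nu)) || any(nu < 0) || any(nu >= 0.5)) {
    stop("nu must lie in [0, 0.5)", call. = FALSE)
  }
  invisible(NULL)
}

# Section stiffness for a geometry/material pair; single point where the
# solvers obtain (k_b, k_t).
geom_stiffness <- function(geom, mat) {
  section_stiffness(mat$E, mat$nu, geom$d_wire)
}
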