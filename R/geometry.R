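#' Arc length of one helix coil
#'
#' The wire length consumed by a single complete coil of a helix with
#' (centerline) diameter `d` and pitch `p`: `sqrt(pi^2 d^2 + p^2)`.
#' Degenerate limits are admitted: `p = 0` is a closed circle of
#' circumference `pi d`, `d = 0` is a straight wire of length `p`.
#'
#' @param d helix centerline diameter (length units, >= 0).
#' @param p pitch, the axial advance per coil (length units, >= 0).
#' @return coil arc length in the same length units.
#' @examples
#' coil_length(12.7e-3, 18.6e-3)   # one coil of the in vivo stent, metres
#' @export
coil_length <- function(d, p) {
  check_nonneg(d, "d")
  check_nonneg(p, "p")
  if (any(d == 0 & p == 0)) stop("d and p cannot both be zero", call. = FALSE)
  sqrt(pi^2 * d^2 + p^2)
}

#' Body-frame curvature vector of a helix
#'
#' For a helix of diameter `d` and pitch `p`, parameterized by arc length
#' with the body frame's z-axis tangent to the wire and x-axis pointing at
#' the helix center, the curvature vector is
#' `u = (0, 2 pi^2 d / c^2, 2 pi p / c^2)` with `c = coil_length(d, p)`.
#' The second component is the bending rate, the third the twisting rate;
#' the first vanishes identically for a helix. `norm(u) * c == 2 pi` holds
#' for every admissible `(d, p)`.
#'
#' @param d helix diameter (> 0).
#' @param p pitch (>= 0); `p = 0` gives a circle with curvature `2/d` and
#'   zero twist.
#' @return numeric length-3 vector, units 1/length.
#' @export
curvature_vector <- function(d, p) {
  check_pos(d, "d")
  check_nonneg(p, "p")
  c2 <- pi^2 * d^2 + p^2
  c(0, 2 * pi^2 * d / c2, 2 * pi * p / c2)
}

#' Helix angle from diameter and pitch
#'
#' The angle between a coil and the plane normal to the helix axis,
#' `atan(p / (pi d))`, in (0, 90) degrees. Small angles are nearly
#' circular coils; large angles are stretched-out helices.
#'
#' @param d helix diameter (> 0).
#' @param p pitch (> 0).
#' @param degrees return degrees (default) or radians.
#' @return helix angle.
#' @examples
#' helix_angle(12.7e-3, 18.6e-3)   # ~25 degrees
#' @export
helix_angle <- function(d, p, degrees = TRUE) {
  check_pos(d, "d")
  check_pos(p, "p")
  a <- atan(p / (pi * d))
  if (degrees) rad_to_deg(a) else a
}

#' Pitch that realizes a helix angle on a reference diameter
#'
#' Inverse of [helix_angle()]: `p = pi * d_ref * tan(theta)`. Design sweeps
#' convert angle grids to pitch grids on the shape-setting template
#' diameter, so that one angle grid yields one pitch grid shared by all
#' wire diameters.
#'
#' @param d_ref reference diameter (> 0), typically the template diameter.
#' @param theta helix angle, strictly between 0 and 90 degrees.
#' @param degrees is `theta` in degrees (default) or radians.
#' @return pitch in the units of `d_ref`.
#' @examples
#' pitch_from_angle(12.7e-3, 25)   # 18.6 mm in metres
#' @export
pitch_from_angle <- function(d_ref, theta, degrees = TRUE) {
  check_pos(d_ref, "d_ref")
  th <- if (degrees) deg_to_rad(theta) else theta
  if (any(!is.finite(th)) || any(th <= 0) || any(th >= pi / 2)) {
    stop("theta must lie strictly between 0 and 90 degrees", call. = FALSE)
  }
  pi * d_ref * tan(th)
}

#' Undeformed helical stent geometry
#'
#' Bundles the design parameters of a helical wire stent with the derived
#' kinematic quantities the deformation model needs: the single-coil arc
#' length `c0`, the total wire length `l = n_coils * c0` (the wire is
#' treated as inextensible, so `l` is invariant under deformation), and the
#' intrinsic (stress-free) curvature vector `u_hat`.
#'
#' `d0` is the wire-centerline helix diameter; the stent outer diameter is
#' `d0 + d_wire` and is stored for reporting.
#'
#' @param d0 unloaded helix (centerline) diameter (> 0).
#' @param p0 unloaded pitch (> 0).
#' @param d_wire wire diameter (> 0, < `d0`).
#' @param n_coils number of complete coils (> 0, need not be integer).
#' @return an object of class `helix_geometry`: a list with fields `d0`,
#'   `p0`, `d_wire`, `n_coils`, `c0`, `l`, `u_hat`, `outer_d`.
#' @examples
#' helix_geometry(d0 = 13.21e-3, p0 = 18.6e-3, d_wire = 0.51e-3, n_coils = 3)
#' @export
helix_geometry <- function(d0, p0, d_wire, n_coils = 3) {
  check_pos(d0, "d0"); check_pos(p0, "p0")
  check_pos(d_wire, "d_wire"); check_pos(n_coils, "n_coils")
  if (d_wire >= d0) stop("d_wire must be smaller than d0", call. = FALSE)
  c0 <- coil_length(d0, p0)
  geom <- list(
    d0 = d0, p0 = p0, d_wire = d_wire, n_coils = n_coils,
    c0 = c0, l = n_coils * c0, u_hat = curvature_vector(d0, p0),
    outer_d = d0 + d_wire
  )
  class(geom) <- "helix_geometry"
  geom
}

#' @export
print.helix_geometry <- function(x, ...) {
  cat("Helical stent geometry\n")
  cat(sprintf("  helix diameter d0 : %g (outer %g)\n", x$d0, x$outer_d))
  cat(sprintf("  pitch p0          : %g  (helix angle %.2f deg)\n",
              x$p0, helix_angle(x$d0, x$p0)))
  cat(sprintf("  wire diameter     : %g\n", x$d_wire))
  cat(sprintf("  coils             : %g  (wire length %g)\n", x$n_coils, x$l))
  invisible(x)
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("%s must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("%s must be non-negative and finite", name), call. = FALSE)
  }
  invisible(x)
}
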