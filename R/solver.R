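#' Coefficients of the pitch stationarity quartic
#'
#' Setting dE/dp = 0 for the helical-constraint elastic energy at fixed
#' diameter `d` reduces, after clearing the positive factor `2 pi l / c^6`,
#' to the quartic `a0 + a1 p + a2 p^2 + a3 p^3 + a4 p^4 = 0` with
#' \itemize{
#'   \item `a0 = -k_t u_hat_z pi^4 d^4`
#'   \item `a1 = 2 pi^3 d^2 (k_t - 2 k_b + k_b u_hat_y d)`
#'   \item `a2 = 0`
#'   \item `a3 = 2 pi (k_b u_hat_y d - k_t)`
#'   \item `a4 = k_t u_hat_z`
#' }
#' Exposed mainly so the stationarity condition can be checked directly
#' against numerical energy minimization.
#'
#' @inheritParams elastic_energy
#' @return numeric vector `c(a0, a1, a2, a3, a4)`; `a2` is exactly 0 and
#'   `a4 > 0`.
#' @export
pitch_polynomial <- function(geom, mat, d) {
  stopifnot(inherits(geom, "helix_geometry"), inherits(mat, "wire_material"))
  check_pos(d, "d")
  ks <- geom_stiffness(geom, mat)
  uy <- geom$u_hat[2]
  uz <- geom$u_hat[3]
  c(-ks$k_t * uz * pi^4 * d^4,
    2 * pi^3 * d^2 * (ks$k_t - 2 * ks$k_b + ks$k_b * uy * d),
    0,
    2 * pi * (ks$k_b * uy * d - ks$k_t),
    ks$k_t * uz)
}

# All real positive roots of a0 + a1 p + ... + a4 p^4, via the companion
# matrix eigenvalue route. Roots with relative imaginary part below im_tol
# are treated as real; kept roots get two Newton polish steps.
quartic_positive_roots <- function(a, im_tol = 1e-9) {
  a <- a / a[5]
  comp <- matrix(0, 4, 4)
  comp[cbind(2:4, 1:3)] <- 1
  comp[, 4] <- -a[1:4]
  ev <- eigen(comp, only.values = TRUE)$values
  real <- abs(Im(ev)) <= im_tol * pmax(1, abs(ev))
  roots <- Re(ev[real & Re(ev) > 0])
  if (length(roots) == 0L) return(list(roots = numeric(0), all = ev))
  for (i in seq_len(2)) {
    f <- a[1] + roots * (a[2] + roots * (a[3] + roots * (a[4] + roots)))
    fp <- a[2] + roots * (2 * a[3] + roots * (3 * a[4] + 4 * roots))
    step <- ifelse(fp != 0, f / fp, 0)
    roots <- roots - step
  }
  list(roots = roots[roots > 0], all = ev)
}

#' Equilibrium pitch at a prescribed helix diameter
#'
#' Among the positive real roots of the stationarity quartic
#' ([pitch_polynomial()]), returns the pitch with minimal elastic energy —
#' the pitch the stent adopts when its diameter is held at `d`. Radial
#' compression (`d < d0`) lengthens the stent: the returned pitch exceeds
#' `p0` and grows as `d` shrinks.
#'
#' @inheritParams elastic_energy
#' @param d prescribed helix diameter, `0 < d <= d0`.
#' @return equilibrium pitch (length units).
#' @export
equilibrium_pitch <- function(geom, mat, d) {
  stopifnot(inherits(geom, "helix_geometry"), inherits(mat, "wire_material"))
  check_diameter(geom, d)
  equilibrium_pitch_unchecked(geom, mat, d)
}

# Core without the d <= d0 guard: the Newton solver needs evaluations a
# fraction of a finite-difference step above d0.
equilibrium_pitch_unchecked <- function(geom, mat, d) {
  a <- pitch_polynomial(geom, mat, d)
  rts <- quartic_positive_roots(a)
  if (length(rts$roots) == 0L) {
    stop(sprintf(
      "infeasible geometry: stationarity quartic has no positive real root at d = %g (roots: %s)",
      d, paste(format(rts$all, digits = 6), collapse = ", ")), call. = FALSE)
  }
  ks <- geom_stiffness(geom, mat)
  en <- energy_dp(geom, ks, d, rts$roots)
  best <- min(en)
  # near-ties resolve to the root closest to p0 (continuity of the
  # deformation path)
  cand <- rts$roots[en <= best * (1 + 1e-12) + .Machine$double.xmin]
  cand[which.min(abs(cand - geom$p0))]
}

check_diameter <- function(geom, d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
    stop("d must be a single positive diameter", call. = FALSE)
  }
  if (d > geom$d0 * (1 + 1e-12)) {
    stop(sprintf("d = %g exceeds the unloaded diameter d0 = %g", d, geom$d0),
         call. = FALSE)
  }
  invisible(d)
}

# Signed radial line force in the body frame (x-axis toward the helix
# center). Positive under compression, i.e. the distributed tissue load is
# directed radially inward; vanishes at the stress-free shape.
line_force_signed <- function(geom, ks, d, p) {
  u <- curvature_vector(d, p)
  uh <- geom$u_hat
  (u[2]^2 + u[3]^2) / u[3] *
    ((ks$k_t - ks$k_b) * u[2] * u[3] - ks$k_t * uh[3] * u[2] + ks$k_b * uh[2] * u[3])
}

#' Radial contact line force at a prescribed diameter
#'
#' Magnitude of the distributed radial force (per unit wire length) that
#' holds the stent at diameter `d` with its equilibrium pitch. Obtained in
#' closed form from the Cosserat rod equilibrium of a helix under a purely
#' radial, frictionless distributed load:
#' `f_x = ((u_y^2 + u_z^2) / u_z) ((k_t - k_b) u_y u_z - k_t u_hat_z u_y + k_b u_hat_y u_z)`
#' evaluated at the deformed curvature. In the body frame the x-axis points
#' at the helix center, and `f_x` is positive under compression: the
#' returned magnitude is the radially inward load the stent resists.
#' Linear in the section stiffnesses, zero at `d = d0`.
#'
#' @inheritParams equilibrium_pitch
#' @return force per unit length (force/length units, >= 0).
#' @export
contact_line_force <- function(geom, mat, d) {
  stopifnot(inherits(geom, "helix_geometry"), inherits(mat, "wire_material"))
  check_diameter(geom, d)
  if (d >= geom$d0) return(0)   # stress-free: the closed form vanishes
  ks <- geom_stiffness(geom, mat)
  p <- equilibrium_pitch_unchecked(geom, mat, d)
  abs(line_force_signed(geom, ks, d, p))
}

#' External pressure supported at a prescribed diameter
#'
#' Converts the radial contact line force back to the uniform external
#' pressure it balances. Each coil of deformed diameter `d` and pitch `p`
#' supports the pressure acting on a band of the stented cylinder, giving
#' `rho = f sqrt(p^2 + pi^2 d^2) / (pi d p)`, the inverse of the
#' pressure-to-line-force projection. Zero at `d = d0`, increasing as the
#' stent is compressed.
#'
#' @inheritParams equilibrium_pitch
#' @return pressure (pressure units, >= 0).
#' @export
pressure_for_diameter <- function(geom, mat, d) {
  stopifnot(inherits(geom, "helix_geometry"), inherits(mat, "wire_material"))
  check_diameter(geom, d)
  if (d >= geom$d0) return(0)
  max(0, pressure_signed(geom, mat, d))
}

pressure_signed <- function(geom, mat, d) {
  ks <- geom_stiffness(geom, mat)
  p <- equilibrium_pitch_unchecked(geom, mat, d)
  line_force_signed(geom, ks, d, p) * coil_length(d, p) / (pi * d * p)
}

#' One equilibrium state of the pressured stent
#'
#' Assembles the full deformed state at diameter `d`: equilibrium pitch,
#' deformed coil length and curvature, stored elastic energy, radial line
#' force, supported pressure and normalized cross-sectional area
#' `(d / d0)^2`.
#'
#' @inheritParams equilibrium_pitch
#' @return an object of class `deformed_state`.
#' @export
deformed_state <- function(geom, mat, d) {
  stopifnot(inherits(geom, "helix_geometry"), inherits(mat, "wire_material"))
  check_diameter(geom, d)
  d <- min(d, geom$d0)
  ks <- geom_stiffness(geom, mat)
  p <- if (d == geom$d0) geom$p0 else equilibrium_pitch_unchecked(geom, mat, d)
  u <- curvature_vector(d, p)
  f <- abs(line_force_signed(geom, ks, d, p))
  st <- list(
    d = d, p = p, c = coil_length(d, p), u = u,
    energy = energy_dp(geom, ks, d, p),
    f_line = f,
    pressure = if (d == geom$d0) 0 else f * coil_length(d, p) / (pi * d * p),
    area_ratio = (d / geom$d0)^2,
    geometry = geom, material = mat
  )
  class(st) <- "deformed_state"
  st
}

#' @export
print.deformed_state <- function(x, ...) {
  g <- x$geometry
  cat("Deformed stent state\n")
  cat(sprintf("  pressure    : %g  (%.4g cmH2O if SI)\n",
              x$pressure, pressure_convert(x$pressure, "Pa", "cmH2O")))
  cat(sprintf("  diameter    : %g  (d0 = %g)\n", x$d, g$d0))
  cat(sprintf("  pitch       : %g  (p0 = %g)\n", x$p, g$p0))
  cat(sprintf("  area ratio  : %.5f  (%.2f%% reduction)\n",
              x$area_ratio, 100 * (1 - x$area_ratio)))
  cat(sprintf("  line force  : %g   energy: %g\n", x$f_line, x$energy))
  invisible(x)
}

#' Deformed stent diameter under a uniform external pressure
#'
#' Inverts the pressure-diameter relation: finds the diameter `d` at which
#' the supported pressure equals `rho`. A Newton iteration from `d = d0`
#' (numerical central-difference derivative, step `1e-8 d0`) is used, with
#' a bracketing-bisection fallback on `[d_lo, d0]` (initial
#' `d_lo = 0.5 d0`, halved while the bracket does not straddle) whenever a
#' Newton iterate leaves the admissible interval or stalls. Convergence:
#' `|delta d| < tol_d` (default `1e-10` in the length unit in use, i.e.
#' 1e-10 m in SI) or 100 iterations.
#'
#' Only compression is modelled; `rho < 0` is rejected.
#'
#' @inheritParams elastic_energy
#' @param rho external pressure (>= 0, pressure units consistent with `mat`).
#' @param d_init optional initial guess (defaults to `d0`; sweeps warm-start
#'   from the previous solution).
#' @param tol_d absolute convergence tolerance on diameter.
#' @return a [deformed_state()] with `pressure` equal to `rho` (to solver
#'   tolerance).
#' @export
diameter_under_pressure <- function(geom, mat, rho, d_init = NULL,
                                    tol_d = 1e-10) {
  stopifnot(inherits(geom, "helix_geometry"), inherits(mat, "wire_material"))
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho)) {
    stop("rho must be a single finite pressure", call. = FALSE)
  }
  if (rho < 0) {
    stop("rho must be >= 0: expansion under negative transmural pressure is not modelled",
         call. = FALSE)
  }
  if (rho == 0) return(deformed_state(geom, mat, geom$d0))

  d0 <- geom$d0
  g <- function(d) pressure_signed(geom, mat, d) - rho
  h <- 1e-8 * d0
  d <- if (is.null(d_init)) d0 else min(max(d_init, 1e-3 * d0), d0)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(100L)) {
    gd <- g(d)
    dg <- (g(min(d + h, d0 * (1 + 2e-8))) - g(d - h)) / # signed form is smooth through d0
      (min(d + h, d0 * (1 + 2e-8)) - (d - h))
    if (!is.finite(dg) || dg == 0) break
    dn <- d - gd / dg
    trace <- c(trace, dn)
    if (!is.finite(dn) || dn <= 0.05 * d0 || dn > d0) break
    if (abs(dn - d) < tol_d) {
      d <- dn
      converged <- TRUE
      break
    }
    d <- dn
  }
  if (!converged) d <- bisect_diameter(g, d0, tol_d, trace)
  deformed_state(geom, mat, min(d, d0))
}

bisect_diameter <- function(g, d0, tol_d, trace) {
  d_lo <- 0.5 * d0
  g_hi <- g(d0)                       # = -rho < 0
  g_lo <- g(d_lo)
  while (g_lo < 0 && d_lo > 0.01 * d0) {
    d_lo <- d_lo / 2
    g_lo <- g(d_lo)
  }
  if (g_lo < 0) {
    stop(paste0(
      "pressure-diameter inversion failed: pressure not attained above d = ",
      format(d_lo), "; Newton trace: ",
      paste(format(utils::tail(trace, 5)), collapse = ", ")), call. = FALSE)
  }
  hi <- d0
  lo <- d_lo
  while (hi - lo > tol_d) {
    mid <- (hi + lo) / 2
    if (g(mid) < 0) hi <- mid else lo <- mid
  }
  (hi + lo) / 2
}

#' Pressure sweep of a stent
#'
#' Solves [diameter_under_pressure()] on an equally spaced pressure grid
#' from 0 to `rho_max` and returns the resulting pressure-deformation
#' curve. The first row is the identity (unloaded) state. The normalized
#' area is checked to be non-increasing along the sweep; a violation aborts
#' with a diagnostic, since it would make the pressure-diameter relation
#' multivalued.
#'
#' @inheritParams diameter_under_pressure
#' @param rho_max maximum pressure (> 0).
#' @param n_points number of pressures (>= 2).
#' @return an object of classes `pressure_curve` and `data.frame` with
#'   columns `pressure`, `d`, `p`, `helix_angle_deg`, `area_ratio`,
#'   `f_line`, `energy` (input units; SI in, SI out), and the geometry and
#'   material attached as attributes.
#' @export
pressure_sweep <- function(geom, mat, rho_max, n_points = 51) {
  stopifnot(inherits(geom, "helix_geometry"), inherits(mat, "wire_material"))
  check_pos(rho_max, "rho_max")
  if (!is.numeric(n_points) || n_points < 2) {
    stop("n_points must be at least 2", call. = FALSE)
  }
  rhos <- seq(0, rho_max, length.out = as.integer(n_points))
  d_prev <- geom$d0
  rows <- vector("list", length(rhos))
  for (i in seq_along(rhos)) {
    st <- tryCatch(
      diameter_under_pressure(geom, mat, rhos[i], d_init = d_prev),
      error = function(e) {
        stop(sprintf("pressure sweep failed at rho = %g: %s",
                     rhos[i], conditionMessage(e)), call. = FALSE)
      })
    d_prev <- st$d
    rows[[i]] <- data.frame(
      pressure = rhos[i], d = st$d, p = st$p,
      helix_angle_deg = helix_angle(st$d, st$p),
      area_ratio = st$area_ratio, f_line = st$f_line, energy = st$energy
    )
  }
  curve <- do.call(rbind, rows)
  if (any(diff(curve$area_ratio) > 1e-12)) {
    bad <- which(diff(curve$area_ratio) > 1e-12)[1]
    stop(sprintf(
      "area ratio increased between rho = %g and rho = %g: pressure-diameter relation not monotone",
      curve$pressure[bad], curve$pressure[bad + 1]), call. = FALSE)
  }
  attr(curve, "geometry") <- geom
  attr(curve, "material") <- mat
  class(curve) <- c("pressure_curve", "data.frame")
  curve
}
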