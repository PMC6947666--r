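#' Wire-diameter x helix-angle design table
#'
#' Enumerates candidate stent designs on a grid of wire diameters and helix
#' angles, evaluates each at a reference external pressure, and returns one
#' row per design. For each pair, the unloaded pitch is set on the template
#' diameter (`p0 = pi * d_template * tan(theta)`), the unloaded helix
#' diameter is `d0 = d_template + d_wire` (the wire centerline sits one
#' wire radius off the template on which the stent is shape-set, on both
#' sides), and the outer diameter is `d0 + d_wire`.
#'
#' @param d_template template (shape-setting mandrel) diameter. Default
#'   12.7e-3 (metres).
#' @param wire_diameters vector of wire diameters. Default
#'   `c(0.38e-3, 0.51e-3)`.
#' @param thetas vector of helix angles in degrees. Default
#'   `c(15, 20, 25, 30, 35)`.
#' @param rho_ref reference external pressure (>= 0). Default 10 cmH2O in
#'   Pa.
#' @param mat a [wire_material()].
#' @param n_coils coils per stent (irrelevant to the predicted area ratio,
#'   which is per-unit-length; kept for reporting).
#' @return an object of classes `design_table` and `data.frame` with
#'   columns `d_wire`, `theta_deg`, `p0`, `d0`, `outer_d`,
#'   `area_ratio_at_ref` and attribute `rho_ref`.
#' @examples
#' \donttest{
#' build_design_table(mat = wire_material())
#' }
#' @export
build_design_table <- function(d_template = 12.7e-3,
                               wire_diameters = c(0.38e-3, 0.51e-3),
                               thetas = c(15, 20, 25, 30, 35),
                               rho_ref = pressure_convert(10, "cmH2O", "Pa"),
                               mat = wire_material(),
                               n_coils = 3) {
  check_pos(d_template, "d_template")
  check_pos(wire_diameters, "wire_diameters")
  if (length(wire_diameters) == 0L || length(thetas) == 0L) {
    stop("wire_diameters and thetas must be nonempty", call. = FALSE)
  }
  check_nonneg(rho_ref, "rho_ref")
  stopifnot(inherits(mat, "wire_material"))

  grid <- expand.grid(theta = thetas, d_wire = wire_diameters,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    dw <- grid$d_wire[i]
    th <- grid$theta[i]
    p0 <- pitch_from_angle(d_template, th)
    geom <- helix_geometry(d0 = d_template + dw, p0 = p0, d_wire = dw,
                           n_coils = n_coils)
    ar <- if (rho_ref == 0) 1 else {
      st <- tryCatch(diameter_under_pressure(geom, mat, rho_ref),
                     error = function(e) {
                       stop(sprintf(
                         "design row (d_wire = %g, theta = %g deg) failed: %s",
                         dw, th, conditionMessage(e)), call. = FALSE)
                     })
      st$area_ratio
    }
    data.frame(d_wire = dw, theta_deg = th, p0 = p0, d0 = geom$d0,
               outer_d = geom$outer_d, area_ratio_at_ref = ar)
  })
  tbl <- do.call(rbind, rows)
  attr(tbl, "rho_ref") <- rho_ref
  attr(tbl, "d_template") <- d_template
  attr(tbl, "material") <- mat
  class(tbl) <- c("design_table", "data.frame")
  tbl
}

# area ratio of a single (template, wire, pitch) design at pressure rho
design_area_ratio <- function(d_template, d_wire, p0, mat, rho) {
  geom <- helix_geometry(d0 = d_template + d_wire, p0 = p0, d_wire = d_wire)
  diameter_under_pressure(geom, mat, rho)$area_ratio
}

#' Maximum pitch meeting a target area reduction
#'
#' Solves the upper end of the design pitch window: the pitch at which the
#' stent's predicted cross-sectional area reduction under pressure `rho`
#' equals `target_area_reduction` (reduction defined as
#' `1 - (d/d0)^2` on the centerline helix diameter). Any larger pitch
#' (softer stent) would let the airway collapse further than the target.
#'
#' The area ratio at fixed pressure is verified to decrease monotonically
#' in pitch over the bracket before bisecting.
#'
#' @param d_template template diameter (default 12.7e-3 m).
#' @param d_wire wire diameter.
#' @param mat a [wire_material()].
#' @param rho evaluation pressure (default 10 cmH2O in Pa).
#' @param target_area_reduction fractional reduction in (0, 1), e.g. 0.30.
#' @param bracket pitch search interval; default helix angles 5-60 degrees
#'   on the template.
#' @param pitch_tol bisection tolerance on pitch (default 1e-5 in the
#'   length unit in use, i.e. 0.01 mm in SI).
#' @return the criterion pitch (length units).
#' @export
max_pitch_for_target_reduction <- function(d_template = 12.7e-3, d_wire,
                                           mat = wire_material(),
                                           rho = pressure_convert(10, "cmH2O", "Pa"),
                                           target_area_reduction,
                                           bracket = pitch_from_angle(d_template, c(5, 60)),
                                           pitch_tol = 1e-5) {
  if (!is.numeric(target_area_reduction) || length(target_area_reduction) != 1L ||
      target_area_reduction <= 0 || target_area_reduction >= 1) {
    stop("target_area_reduction must lie strictly in (0, 1)", call. = FALSE)
  }
  check_pos(rho, "rho")
  target_ratio <- 1 - target_area_reduction
  f <- function(p) design_area_ratio(d_template, d_wire, p, mat, rho) - target_ratio
  solve_pitch_monotone(f, bracket, pitch_tol, increasing = FALSE,
                       what = "target area reduction")
}

#' Largest pitch insensitive to wire diameter
#'
#' Solves the lower end of the design pitch window: the largest pitch at
#' which the two candidate wire diameters predict cross-sectional area
#' ratios within `tol` of each other at pressure `rho`. Below this pitch
#' the thin and thick wires perform near-identically, so the smaller wire
#' diameter (less foreign material, less mucus interruption) gains nothing
#' from a stiffer neighbor — pitches below it are not worth trading mucus
#' transport for.
#'
#' The area-ratio difference is verified to increase monotonically in
#' pitch over the bracket before bisecting.
#'
#' @param d_template template diameter (default 12.7e-3 m).
#' @param d_wire_small,d_wire_large the two wire diameters,
#'   `d_wire_small < d_wire_large`.
#' @param mat a [wire_material()].
#' @param rho evaluation pressure (default 10 cmH2O in Pa).
#' @param tol maximum admissible area-ratio difference, in (0, 1); e.g.
#'   0.05.
#' @param bracket pitch search interval; default helix angles 5-45 degrees
#'   on the template. The area-ratio difference between the two wires only
#'   grows with pitch while both stents still carry most of the load; at
#'   extreme pitches (beyond ~50 degrees at 10 cmH2O) both collapse nearly
#'   completely and the difference turns over, so the default bracket stays
#'   below that regime.
#' @inheritParams max_pitch_for_target_reduction
#' @return the criterion pitch (length units).
#' @export
wire_insensitive_pitch <- function(d_template = 12.7e-3, d_wire_small,
                                   d_wire_large, mat = wire_material(),
                                   rho = pressure_convert(10, "cmH2O", "Pa"),
                                   tol = 0.05,
                                   bracket = pitch_from_angle(d_template, c(5, 45)),
                                   pitch_tol = 1e-5) {
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0 || tol >= 1) {
    stop("tol must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!(d_wire_small < d_wire_large)) {
    stop("d_wire_small must be smaller than d_wire_large", call. = FALSE)
  }
  check_pos(rho, "rho")
  f <- function(p) {
    abs(design_area_ratio(d_template, d_wire_small, p, mat, rho) -
          design_area_ratio(d_template, d_wire_large, p, mat, rho)) - tol
  }
  # difference grows with pitch; the largest pitch still within tol is the
  # root of f
  if (f(bracket[2]) <= 0) return(bracket[2])
  solve_pitch_monotone(f, bracket, pitch_tol, increasing = TRUE,
                       what = "wire-insensitivity")
}

# bisection with a monotonicity pre-check on a coarse scan
solve_pitch_monotone <- function(f, bracket, pitch_tol, increasing, what,
                                 n_scan = 7) {
  stopifnot(length(bracket) == 2L, bracket[1] > 0, bracket[1] < bracket[2])
  ps <- seq(bracket[1], bracket[2], length.out = n_scan)
  vals <- vapply(ps, f, numeric(1))
  dv <- diff(vals)
  ok <- if (increasing) all(dv > 0) else all(dv < 0)
  if (!ok) {
    stop(sprintf("%s criterion: objective is not monotone over the pitch bracket [%g, %g]",
                 what, bracket[1], bracket[2]), call. = FALSE)
  }
  if (vals[1] * vals[n_scan] > 0) {
    stop(sprintf(
      "%s criterion has no solution in the pitch bracket [%g, %g]: objective spans [%g, %g]",
      what, bracket[1], bracket[2], min(vals), max(vals)), call. = FALSE)
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- vals[1]
  while (hi - lo > pitch_tol) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Select a stent diameter for a measured trachea
#'
#' Picks, from the available stent helix diameters, the smallest one at
#' least as large as the measured tracheal inner diameter, so the deployed
#' stent is preloaded against the tracheal wall (resisting migration)
#' while oversizing is minimal. Warns when the preload margin exceeds
#' `margin_cap`.
#'
#' @param available_d0 nonempty vector of candidate stent diameters.
#' @param trachea_d measured tracheal inner diameter (> 0), same units.
#' @param margin_cap warn when `selected - trachea_d` exceeds this
#'   (default 2e-3, i.e. 2 mm in SI).
#' @return a list of class `stent_selection` with `selected`, `margin`,
#'   `candidates`, `trachea_d`.
#' @examples
#' select_stent(c(10.03, 11.62, 13.21, 14.80, 16.38) * 1e-3, 13.2e-3)
#' @export
select_stent <- function(available_d0, trachea_d, margin_cap = 2e-3) {
  check_pos(available_d0, "available_d0")
  check_pos(trachea_d, "trachea_d")
  if (length(available_d0) == 0L) stop("available_d0 is empty", call. = FALSE)
  fits <- available_d0[available_d0 >= trachea_d]
  if (length(fits) == 0L) {
    stop(sprintf(
      "no available stent diameter fits: largest candidate %g < trachea %g",
      max(available_d0), trachea_d), call. = FALSE)
  }
  sel <- min(fits)
  margin <- sel - trachea_d
  if (margin > margin_cap) {
    warning(sprintf("preload margin %g exceeds cap %g: stent may be oversized",
                    margin, margin_cap), call. = FALSE)
  }
  structure(list(selected = sel, margin = margin,
                 candidates = sort(available_d0), trachea_d = trachea_d),
            class = "stent_selection")
}

#' @export
print.stent_selection <- function(x, ...) {
  cat(sprintf("Selected stent diameter %g for trachea %g (preload margin %g)\n",
              x$selected, x$trachea_d, x$margin))
  invisible(x)
}
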