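#' Write a pressure-deformation curve to CSV
#'
#' Serializes a [pressure_sweep()] result. The curve is assumed to be in SI
#' units (m, Pa, N, J); columns are written as
#' `pressure_cmH2O, pressure_Pa, diameter_mm, pitch_mm, helix_angle_deg,
#' area_ratio, line_force_N_per_m, energy_J` at 9 significant digits. The
#' resolved configuration (geometry and material, including defaulted
#' constants) is embedded as `#`-prefixed header lines so the file is
#' reproducible on its own.
#'
#' @param curve a `pressure_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pressure_curve <- function(curve, path) {
  stopifnot(inherits(curve, "pressure_curve"))
  out <- data.frame(
    pressure_cmH2O = pressure_convert(curve$pressure, "Pa", "cmH2O"),
    pressure_Pa = curve$pressure,
    diameter_mm = m_to_mm(curve$d),
    pitch_mm = m_to_mm(curve$p),
    helix_angle_deg = curve$helix_angle_deg,
    area_ratio = curve$area_ratio,
    line_force_N_per_m = curve$f_line,
    energy_J = curve$energy
  )
  write_annotated_csv(out, path,
                      config_lines(attr(curve, "geometry"),
                                   attr(curve, "material")))
}

#' Write a design table to CSV
#'
#' Serializes a [build_design_table()] result (SI in). Columns:
#' `wire_mm, angle_deg, pitch_mm, d0_mm, outer_d_mm, area_ratio_at_ref,
#' pressure_ref_cmH2O`, 9 significant digits, with the resolved
#' configuration embedded as `#` header lines.
#'
#' @param tbl a `design_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "design_table"))
  rho_ref <- attr(tbl, "rho_ref")
  out <- data.frame(
    wire_mm = m_to_mm(tbl$d_wire),
    angle_deg = tbl$theta_deg,
    pitch_mm = m_to_mm(tbl$p0),
    d0_mm = m_to_mm(tbl$d0),
    outer_d_mm = m_to_mm(tbl$outer_d),
    area_ratio_at_ref = tbl$area_ratio_at_ref,
    pressure_ref_cmH2O = pressure_convert(rho_ref, "Pa", "cmH2O")
  )
  mat <- attr(tbl, "material")
  head <- c(sprintf("# d_template_mm: %.9g", m_to_mm(attr(tbl, "d_template"))),
            sprintf("# rho_ref_Pa: %.9g", rho_ref),
            sprintf("# E_Pa: %.9g", mat$E),
            sprintf("# nu: %.9g", mat$nu))
  write_annotated_csv(out, path, head)
}

write_annotated_csv <- function(df, path, header_lines) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 9)
  if (inherits(path, "connection")) {
    con <- path
  } else {
    con <- file(path, "w")
    on.exit(close(con))
  }
  writeLines(header_lines, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

config_lines <- function(geom, mat) {
  c(sprintf("# d0_mm: %.9g", m_to_mm(geom$d0)),
    sprintf("# p0_mm: %.9g", m_to_mm(geom$p0)),
    sprintf("# d_wire_mm: %.9g", m_to_mm(geom$d_wire)),
    sprintf("# n_coils: %.9g", geom$n_coils),
    sprintf("# E_Pa: %.9g", mat$E),
    sprintf("# nu: %.9g", mat$nu))
}

#' Read a run configuration file
#'
#' Reads a plain-text YAML key-value configuration. Recognized keys mirror
#' the CLI flags (`template_mm`, `wire_mm`, `angle_deg`, `pitch_mm`,
#' `coils`, `E_gpa`, `nu`, `pressure`, `rho_max`, `n_points`, `out`, ...);
#' unknown keys are kept and passed through, CLI flags override config
#' values.
#'
#' @param path path to a YAML file.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must contain a key-value mapping",
                          call. = FALSE)
  cfg
}

#' Seeded random admissible test cases
#'
#' Draws `n` admissible (geometry, material, load) cases for property and
#' oracle testing, uniformly over the design-relevant ranges: wire diameter
#' 0.2-1.0 mm, helix angle 10-40 degrees, template diameter 8-20 mm,
#' Young's modulus 40-83 GPa, Poisson ratio 0.2-0.4, pressure
#' (0, 20] cmH2O. Deterministic for a given seed; the caller's RNG state is
#' left untouched.
#'
#' @param seed integer seed.
#' @param n number of cases (> 0).
#' @return list of length `n`; each element has `geom` (a
#'   [helix_geometry()], SI), `mat` (a [wire_material()]) and `rho`
#'   (pressure, Pa).
#' @export
fixture_generator <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(n), n >= 1)
  n <- as.integer(n)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    d_template <- mm_to_m(stats::runif(1, 8, 20))
    d_wire <- mm_to_m(stats::runif(1, 0.2, 1.0))
    theta <- stats::runif(1, 10, 40)
    list(
      geom = helix_geometry(d0 = d_template + d_wire,
                            p0 = pitch_from_angle(d_template, theta),
                            d_wire = d_wire,
                            n_coils = stats::runif(1, 2, 4)),
      mat = wire_material(E = stats::runif(1, 40e9, 83e9),
                          nu = stats::runif(1, 0.2, 0.4)),
      rho = pressure_convert(stats::runif(1, 1e-3, 20), "cmH2O", "Pa")
    )
  })
}
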