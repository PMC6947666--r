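#' Convert between pressure units
#'
#' Converts pressures among the units used in airway-stent work:
#' centimetres of water (`"cmH2O"`, the clinical unit for positive pressure
#' ventilation), pascals (`"Pa"`) and kilopascals (`"kPa"`). The conversion
#' constant is exact by definition: 1 cmH2O = 98.0665 Pa.
#'
#' @param value numeric vector of pressures.
#' @param from,to unit names, one of `"cmH2O"`, `"Pa"`, `"kPa"`.
#' @return numeric vector of the same length as `value`.
#' @examples
#' pressure_convert(10, "cmH2O", "Pa")   # 980.665
#' pressure_convert(980.665, "Pa", "cmH2O")
#' @export
pressure_convert <- function(value, from, to) {
  stopifnot(is.numeric(value))
  pa_per <- c(cmH2O = 98.0665, Pa = 1, kPa = 1000)
  from <- match_unit(from, names(pa_per))
  to <- match_unit(to, names(pa_per))
  if (from == to) return(value)
  value * pa_per[[from]] / pa_per[[to]]
}

match_unit <- function(u, allowed) {
  if (!is.character(u) || length(u) != 1L) {
    stop("pressure unit must be a single string", call. = FALSE)
  }
  hit <- allowed[tolower(allowed) == tolower(u)]
  if (length(hit) != 1L) {
    stop(sprintf("unknown pressure unit '%s' (supported: %s)",
                 u, paste(allowed, collapse = ", ")), call. = FALSE)
  }
  hit
}

# Millimetre/degree helpers used at the CLI boundary; the modelling
# functions themselves are unit-agnostic (any consistent system works,
# SI recommended).
mm_to_m <- function(x) x * 1e-3
m_to_mm <- function(x) x * 1e3
deg_to_rad <- function(x) x * pi / 180
rad_to_deg <- function(x) x * 180 / pi
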