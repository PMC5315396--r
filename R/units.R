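#' Pressure/stress unit conversion
#'
#' Converts pressures and stresses between the units that appear in the
#' model: clinical blood pressure in mmHg, tissue moduli in N/cm^2 or
#' N/mm^2, and the canonical (g, cm, day) mechanics unit g cm^-1 day^-2.
#'
#' Conversion factors: 1 mmHg = 133.322 Pa, 1 N/cm^2 = 1e4 Pa,
#' 1 N = 1e5 g cm s^-2 and 1 day = 86400 s, so
#' 1 N/cm^2 = 86400^2 * 1e5 g cm^-1 day^-2.
#'
#' @param value numeric vector of pressures.
#' @param from,to one of `"mmHg"`, `"N/cm^2"`, `"N/mm^2"`, `"g/cm/day^2"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_pressure(110, "mmHg", "N/cm^2")   # ~1.4665
#' @export
convert_pressure <- function(value, from, to) {
  stopifnot(is.numeric(value))
  # factors to Pa (SI), then out of Pa
  to_pa <- c(
    "mmHg"       = 133.322,
    "N/cm^2"     = 1e4,
    "N/mm^2"     = 1e6,
    # 1 g/cm/day^2 = 1e-3 kg * 1e-2 m / (86400 s)^2 / (m^2 ... ) ; as a
    # pressure: 1 g cm^-1 day^-2 = 1e-3 kg * (1e-2 m)^-1 * day^-2
    #          = 0.1 kg m^-1 day^-2 = 0.1 / 86400^2 Pa
    "g/cm/day^2" = 0.1 / 86400^2
  )
  if (!from %in% names(to_pa) || !to %in% names(to_pa)) {
    stop("unsupported unit pair: ", from, " -> ", to, call. = FALSE)
  }
  value * to_pa[[from]] / to_pa[[to]]
}
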