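# Unit conversions between SI (used internally) and the clinical units
# quoted at the package interfaces (l, l/min, cm H2O).

#' Physical constants used throughout the package
#'
#' `R_UNIVERSAL` is the universal gas constant (J mol^-1 K^-1) and
#' `PA_PER_CMH2O` the conventional pressure of one centimetre of water
#' (Pa, at standard gravity and 4 degC water density).
#'
#' @name constants
#' @keywords internal
NULL

R_UNIVERSAL <- 8.314462618
PA_PER_CMH2O <- 98.0665

#' Convert between clinical and SI flow and pressure units
#'
#' Flows are handled internally in m^3/s and pressures in Pa; interfaces
#' quote l/min (or l/s) and cm H2O. These helpers convert exactly.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @examples
#' lpm_to_m3s(60)      # 0.001 m^3/s
#' cmh2o_to_pa(1)      # 98.0665 Pa
#' @export
lpm_to_m3s <- function(x) x * 1e-3 / 60

#' @rdname lpm_to_m3s
#' @export
m3s_to_lpm <- function(x) x * 60 * 1e3

#' @rdname lpm_to_m3s
#' @export
lps_to_m3s <- function(x) x * 1e-3

#' @rdname lpm_to_m3s
#' @export
m3s_to_lps <- function(x) x * 1e3

#' @rdname lpm_to_m3s
#' @export
cmh2o_to_pa <- function(x) x * PA_PER_CMH2O

#' @rdname lpm_to_m3s
#' @export
pa_to_cmh2o <- function(x) x / PA_PER_CMH2O
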