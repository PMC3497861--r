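# Ideal-gas mixture densities.  All pressure losses in the model are
# inertial (orifice-type), so density is the only gas property required;
# viscosity is deliberately not modelled.

# Molar masses, g/mol (IUPAC 2021 conventional values)
.BUILTIN_MOLAR_MASS <- c(
  He  = 4.002602,
  N2  = 28.0134,
  O2  = 31.9988,
  CO2 = 44.0095,
  Ar  = 39.948,
  H2  = 2.01588
)

#' Define a gas mixture by mole fractions
#'
#' A gas mixture is a named vector of mole fractions together with a
#' temperature and pressure.  Species named `He`, `N2`, `O2`, `CO2`, `Ar`
#' and `H2` have built-in molar masses; any other species may be supplied
#' through `molar_masses`.
#'
#' The default reference state is dry gas at 20 degC and one standard
#' atmosphere (293.15 K, 101325 Pa), matching bench work with dry,
#' room-temperature medical gases.
#'
#' @param fractions named numeric vector of mole fractions; must be in
#'   \[0, 1\] and sum to 1 within 1e-9.
#' @param temperature absolute temperature, K.
#' @param pressure absolute pressure, Pa.
#' @param molar_masses optional named numeric vector (g/mol) adding to or
#'   overriding the built-in species table.
#' @param name optional label for printing.
#' @return an object of class `gas_mixture`.
#' @examples
#' air <- gas_mixture(c(N2 = 0.78, O2 = 0.22), name = "air")
#' heliox <- gas_mixture(c(He = 0.78, O2 = 0.22), name = "He/O2")
#' mixture_density(air)
#' density_ratio(heliox, air)
#' @seealso [mixture_density()], [density_ratio()]
#' @export
gas_mixture <- function(fractions, temperature = 293.15, pressure = 101325,
                        molar_masses = NULL, name = NULL) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("'fractions' must be a named vector of mole fractions")
  if (any(!is.finite(fractions)) || any(fractions < 0) || any(fractions > 1))
    stop("mole fractions must be finite and lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("mole fractions must sum to 1 (got ", format(sum(fractions)), ")")
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("'temperature' must be a single positive number (K)")
  if (!is.numeric(pressure) || length(pressure) != 1L || pressure <= 0)
    stop("'pressure' must be a single positive number (Pa)")

  mm <- .BUILTIN_MOLAR_MASS
  if (!is.null(molar_masses)) {
    if (is.null(names(molar_masses)) || any(molar_masses <= 0))
      stop("'molar_masses' must be a named vector of positive values (g/mol)")
    mm[names(molar_masses)] <- molar_masses
  }
  unknown <- setdiff(names(fractions), names(mm))
  if (length(unknown))
    stop("unknown species with no molar mass given: ",
         paste(unknown, collapse = ", "))

  structure(
    list(
      fractions = fractions,
      temperature = temperature,
      pressure = pressure,
      molar_mass = unname(sum(fractions * mm[names(fractions)])),
      name = name %||% paste(
        sprintf("%s %.0f%%", names(fractions), 100 * fractions),
        collapse = " / ")
    ),
    class = "gas_mixture"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gas_mixture <- function(x, ...) {
  cat(sprintf("<gas_mixture> %s  M = %.4f g/mol\n", x$name, x$molar_mass))
  cat(sprintf("  T = %.2f K, P = %.0f Pa, rho = %.4f kg/m^3\n",
              x$temperature, x$pressure, mixture_density(x)))
  invisible(x)
}

#' Mass density of a gas mixture
#'
#' Ideal-gas density `rho = P * M / (R * T)` where `M` is the mole-fraction
#' weighted mean molar mass.  Dry, near-ambient gases are assumed; no
#' compressibility factor is applied.
#'
#' @param mix a [gas_mixture()].
#' @return density, kg/m^3.
#' @export
mixture_density <- function(mix) {
  stopifnot(inherits(mix, "gas_mixture"))
  mix$pressure * mix$molar_mass * 1e-3 / (R_UNIVERSAL * mix$temperature)
}

#' Density ratio of two gas mixtures
#'
#' At equal temperature and pressure this reduces exactly to the ratio of
#' mean molar masses; for 78/22 He/O2 over 78/22 N2/O2 air it is ~0.352,
#' the factor by which a purely inertial resistance falls when heliox is
#' substituted for air.
#'
#' @param a,b [gas_mixture()] objects (numerator, denominator).
#' @return dimensionless ratio `rho_a / rho_b`.
#' @export
density_ratio <- function(a, b) {
  mixture_density(a) / mixture_density(b)
}

#' Standard study gases
#'
#' Convenience constructors for the two dry gases used throughout:
#' medical air as 78/22 N2/O2 and heliox as 78/22 He/O2.
#'
#' @param temperature,pressure reference state passed to [gas_mixture()].
#' @return a [gas_mixture()].
#' @export
medical_air <- function(temperature = 293.15, pressure = 101325) {
  gas_mixture(c(N2 = 0.78, O2 = 0.22), temperature, pressure, name = "air 78/22")
}

#' @rdname medical_air
#' @export
heliox <- function(temperature = 293.15, pressure = 101325) {
  gas_mixture(c(He = 0.78, O2 = 0.22), temperature, pressure, name = "He/O2 78/22")
}
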