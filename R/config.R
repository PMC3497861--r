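# YAML configuration describing a complete simulation setup: gas, chamber
# compliances, branch resistors, circuit losses and ventilator settings.

#' Read a simulation configuration from YAML
#'
#' The configuration file has blocks:
#' \preformatted{
#' gas:
#'   species: {He: 0.78, O2: 0.22}
#'   temperature: 293.15        # optional, K
#'   pressure: 101325           # optional, Pa
#' left:  {compliance: 0.05, k: 3.3}     # l/cm H2O, loss coefficient
#' right: {compliance: 0.05, k: 132.9}
#' circuit: {k_fs: 1.2, k_cct: 5.0}      # optional; inertial form
#' ventilator: {tidal_volume: 1.0, rate: 20, ie_ratio: 0.5}
#' allow_pendelluft: true                # optional
#' area: 8.66e-5                         # optional, m^2
#' }
#' Omitted blocks take the package defaults (calibrated shared area,
#' default inertial circuit).
#'
#' @param path YAML file path.
#' @return list with `system` (a [lung_system()]) and `settings` (a
#'   [ventilator_settings()], `NULL` if no `ventilator` block).
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configurations requires the 'yaml' package")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$gas) || is.null(cfg$gas$species))
    stop("configuration must define gas: species")
  gas <- gas_mixture(unlist(cfg$gas$species),
                     temperature = cfg$gas$temperature %||% 293.15,
                     pressure = cfg$gas$pressure %||% 101325)
  area <- cfg$area %||% default_resistor_area()
  k_fs <- cfg$circuit$k_fs %||% 1.2
  circuit <- circuit_loss_model(k_fs = k_fs,
                                k_cct = cfg$circuit$k_cct %||% 5.0,
                                area = area)
  chamber <- function(block, side) {
    if (is.null(block) || is.null(block$compliance) || is.null(block$k))
      stop("configuration must define ", side, ": compliance and k")
    lung_chamber(block$compliance, parabolic_resistor(block$k, area),
                 k_fs = k_fs, volume = block$volume %||% 0)
  }
  sys <- lung_system(chamber(cfg$left, "left"), chamber(cfg$right, "right"),
                     gas = gas, circuit = circuit, area = area,
                     allow_pendelluft = cfg$allow_pendelluft %||% TRUE)
  settings <- if (!is.null(cfg$ventilator))
    ventilator_settings(cfg$ventilator$tidal_volume, cfg$ventilator$rate,
                        cfg$ventilator$ie_ratio %||% 0.5)
  list(system = sys, settings = settings)
}
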