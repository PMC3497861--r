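# Pressure-loss models for the orifice-type components of the test system:
# the parabolic branch resistors, the variable-orifice flow sensors, and the
# expiratory limb of the breathing circuit.
#
# Every component follows the signed quadratic law
#     dP = (k/2) * rho * U |U|,   U = Q / A
# where k is a dimensionless, purely geometric loss coefficient and A the
# entrance cross-sectional area.  The signed form (Q|Q| rather than Q^2)
# keeps the law antisymmetric so reverse (pendelluft) flows are
# representable.

#' Parabolic (orifice-type) resistor
#'
#' @param k dimensionless loss coefficient (> 0); catalogue values for the
#'   Rp5, Rp20 and Rp50 elements are 3.3, 21.5 and 132.9.
#' @param area entrance cross-sectional area, m^2 (> 0).  Vendor tables give
#'   equivalent linear resistances rather than the area; use
#'   [calibrate_area()] to recover it from one table cell.
#' @return an object of class `parabolic_resistor`.
#' @examples
#' A <- calibrate_area(132.9, medical_air(), lpm_to_m3s(60), 108.4)
#' rp50 <- parabolic_resistor(132.9, A)
#' equivalent_linear_resistance(rp50, medical_air(), lpm_to_m3s(20))
#' @export
parabolic_resistor <- function(k, area) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a single positive loss coefficient")
  if (!is.numeric(area) || length(area) != 1L || area <= 0)
    stop("'area' must be a single positive area in m^2")
  structure(list(k = k, area = area), class = "parabolic_resistor")
}

#' @export
print.parabolic_resistor <- function(x, ...) {
  cat(sprintf("<parabolic_resistor> k = %g, area = %.4g m^2 (d = %.1f mm)\n",
              x$k, x$area, 2e3 * sqrt(x$area / pi)))
  invisible(x)
}

# Signed quadratic loss, Pa, for loss coefficient k referenced to area (m^2)
quadratic_dp <- function(k, area, rho, flow) {
  u <- flow / area
  0.5 * k * rho * u * abs(u)
}

#' Pressure drop across a parabolic resistor
#'
#' Signed quadratic loss `dP = (k/2) rho (Q/A)|Q/A|`: positive for forward
#' flow, antisymmetric in the sign of the flow.
#'
#' @param r a [parabolic_resistor()].
#' @param gas a [gas_mixture()] supplying the density.
#' @param flow volumetric flow, m^3/s (any sign).
#' @return pressure drop, Pa (same sign as `flow`).
#' @export
resistor_pressure_drop <- function(r, gas, flow) {
  stopifnot(inherits(r, "parabolic_resistor"))
  quadratic_dp(r$k, r$area, mixture_density(gas), flow)
}

#' Equivalent linear resistance of a quadratic element at a given flow
#'
#' `R = dP / Q` expressed in the clinical unit cm H2O s/l.  For a quadratic
#' element R grows linearly with flow at fixed gas, and linearly with gas
#' density at fixed flow.
#'
#' @inheritParams resistor_pressure_drop
#' @param flow volumetric flow, m^3/s (> 0).
#' @return equivalent resistance, cm H2O s/l.
#' @export
equivalent_linear_resistance <- function(r, gas, flow) {
  if (!is.numeric(flow) || length(flow) != 1L || flow <= 0)
    stop("'flow' must be a single positive flow in m^3/s")
  dp <- resistor_pressure_drop(r, gas, flow)
  pa_to_cmh2o(dp) / m3s_to_lps(flow)
}

#' Calibrate the entrance area from one equivalent-resistance table cell
#'
#' Vendor tables for parabolic resistors quote the loss coefficient `k` and
#' equivalent linear resistances at reference flows, but not the entrance
#' area the quadratic law needs.  Inverting `dP = (k/2) rho (Q/A)^2` with
#' `dP = R Q` gives the unique area reproducing one table cell:
#' `A = Q sqrt(k rho / (2 dP))`.
#'
#' @param k dimensionless loss coefficient.
#' @param gas a [gas_mixture()].
#' @param flow reference flow, m^3/s (> 0).
#' @param resistance quoted equivalent linear resistance, cm H2O s/l (> 0).
#' @return entrance area, m^2.
#' @export
calibrate_area <- function(k, gas, flow, resistance) {
  if (k <= 0 || flow <= 0 || resistance <= 0)
    stop("'k', 'flow' and 'resistance' must all be positive")
  dp <- cmh2o_to_pa(resistance * m3s_to_lps(flow)) # Pa
  flow * sqrt(0.5 * k * mixture_density(gas) / dp)
}

#' Default shared entrance area for the study resistors
#'
#' All parabolic resistors in the study share a common entrance geometry;
#' the area is calibrated once from the Rp50/air/60 l/min table cell
#' (k = 132.9, R = 108.4 cm H2O s/l), the cell quoted with the most
#' significant figures.  Approximately 8.66e-5 m^2 (10.5 mm diameter).
#'
#' @param gas gas at the table's reference state; defaults to dry air at
#'   20 degC, 101.325 kPa.
#' @return area, m^2.
#' @export
default_resistor_area <- function(gas = medical_air()) {
  calibrate_area(132.9, gas, lpm_to_m3s(60), 108.4)
}

#' Catalogue loss coefficients of the study resistors
#'
#' @return named numeric vector of k for the Rp5, Rp20 and Rp50 elements.
#' @export
study_resistor_k <- function() c(Rp5 = 3.3, Rp20 = 21.5, Rp50 = 132.9)

## ---- measured pressure-flow curves ----------------------------------------

#' Measured pressure-drop-versus-flow curve for a circuit component
#'
#' Holds steady-flow bench measurements of the pressure drop across a
#' component (flow sensor, expiratory circuit, ...) for one gas.
#'
#' @param flow flows, m^3/s; nonnegative and strictly increasing.
#' @param pressure_drop pressure drops, Pa; nonnegative.
#' @param gas a [gas_mixture()] identifying the test gas.
#' @param label optional component label.
#' @return an object of class `pressure_flow_curve`.
#' @export
pressure_flow_curve <- function(flow, pressure_drop, gas, label = NULL) {
  if (length(flow) != length(pressure_drop))
    stop("'flow' and 'pressure_drop' must have equal length")
  if (any(flow < 0) || any(diff(flow) <= 0))
    stop("'flow' must be nonnegative and strictly increasing")
  if (any(pressure_drop < 0))
    stop("'pressure_drop' must be nonnegative")
  stopifnot(inherits(gas, "gas_mixture"))
  structure(list(flow = as.numeric(flow),
                 pressure_drop = as.numeric(pressure_drop),
                 gas = gas, label = label),
            class = "pressure_flow_curve")
}

#' Read a pressure-flow curve from CSV
#'
#' Expects columns `flow_lpm` and `dp_cmh2o` with a header row; lines
#' starting with `#` are treated as comments.  Values are converted to SI.
#'
#' @param path CSV file path.
#' @inheritParams pressure_flow_curve
#' @return a [pressure_flow_curve()].
#' @export
read_pressure_flow_csv <- function(path, gas, label = NULL) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("flow_lpm", "dp_cmh2o") %in% names(d)))
    stop("CSV must have columns 'flow_lpm' and 'dp_cmh2o'")
  o <- order(d$flow_lpm)
  pressure_flow_curve(lpm_to_m3s(d$flow_lpm[o]), cmh2o_to_pa(d$dp_cmh2o[o]),
                      gas, label = label)
}

#' Fit a zero-intercept quadratic to a pressure-flow curve
#'
#' Least squares fit of `dP = c1 Q + c2 Q^2` (intercept pinned to zero: a
#' component at rest drops no pressure).  The linear term absorbs any
#' viscous contribution; a purely inertial component has `c1 ~ 0` and
#' `c2 = beta rho`.
#'
#' @param curve a [pressure_flow_curve()] with at least 3 distinct flows.
#' @return a `circuit_loss_model` of form `"polynomial"`, carrying the
#'   coefficients (`c1` in Pa s/m^3, `c2` in Pa s^2/m^6), residuals, and the
#'   gas the fit applies to.
#' @seealso [circuit_pressure_drop()], [circuit_loss_model()]
#' @export
fit_pressure_flow_polynomial <- function(curve) {
  stopifnot(inherits(curve, "pressure_flow_curve"))
  q <- curve$flow; dp <- curve$pressure_drop
  if (length(unique(q)) < 3)
    stop("need at least 3 distinct flow points to fit dP = c1*Q + c2*Q^2")
  fit <- stats::lm(dp ~ 0 + q + I(q^2))
  co <- unname(stats::coef(fit))
  structure(list(form = "polynomial",
                 c1 = co[1], c2 = co[2],
                 gas_name = curve$gas$name,
                 rho_fit = mixture_density(curve$gas),
                 residuals = unname(stats::residuals(fit)),
                 sigma = summary(fit)$sigma,
                 coef_se = unname(summary(fit)$coefficients[, "Std. Error"])),
            class = "circuit_loss_model")
}

#' Circuit loss model in inertial (density-scalable) form
#'
#' Describes the shared expiratory path (flow sensor and breathing circuit)
#' by dimensionless loss coefficients referenced to an entrance area, so the
#' predicted drop `dP = (k/2) rho (Q/A)|Q/A|` transfers across gases through
#' the density alone.  A fitted per-gas polynomial
#' ([fit_pressure_flow_polynomial()]) is the alternative when bench
#' measurements are available; polynomial models apply only to their fitted
#' gas and are never silently rescaled.
#'
#' The default coefficients (`k_fs = 1.2`, `k_cct = 5.0`) are modelling
#' assumptions, not measurements: they place the whole-circuit equivalent
#' resistance for air at 60 l/min near 4 cm H2O s/l, between the Rp5 and
#' Rp20 branch elements, consistent with a circuit whose losses are
#' dominated by the flow sensor and expiratory valve.
#'
#' @param k_fs dimensionless loss coefficient of one flow sensor.
#' @param k_cct dimensionless loss coefficient of the expiratory circuit
#'   (beyond the branch sensors), referenced to the same area.
#' @param area reference entrance area, m^2.
#' @return an object of class `circuit_loss_model`, form `"inertial"`.
#' @export
circuit_loss_model <- function(k_fs = 1.2, k_cct = 5.0,
                               area = default_resistor_area()) {
  if (k_fs < 0 || k_cct < 0 || area <= 0)
    stop("'k_fs' and 'k_cct' must be >= 0 and 'area' > 0")
  structure(list(form = "inertial", k_fs = k_fs, k_cct = k_cct, area = area),
            class = "circuit_loss_model")
}

#' @export
print.circuit_loss_model <- function(x, ...) {
  if (x$form == "inertial")
    cat(sprintf("<circuit_loss_model> inertial: k_fs = %g, k_cct = %g, area = %.4g m^2\n",
                x$k_fs, x$k_cct, x$area))
  else
    cat(sprintf("<circuit_loss_model> polynomial (%s): dP = %.4g Q + %.4g Q^2 [Pa, m^3/s]\n",
                x$gas_name, x$c1, x$c2))
  invisible(x)
}

#' Pressure drop across the expiratory circuit
#'
#' For an inertial-form model the drop is `(k_cct/2) rho (Q/A)|Q/A|` and
#' scales linearly with density, so any gas is accepted.  For a polynomial
#' model the fitted per-gas curve `c1 Q + c2 Q^2` is evaluated (signed), and
#' a gas other than the fitted one is an error: converting requires
#' refitting or an inertial model.
#'
#' @param model a `circuit_loss_model`.
#' @param gas a [gas_mixture()].
#' @param flow volumetric flow, m^3/s (any sign).
#' @return pressure drop, Pa (same sign as `flow`).
#' @export
circuit_pressure_drop <- function(model, gas, flow) {
  stopifnot(inherits(model, "circuit_loss_model"))
  if (model$form == "inertial")
    return(quadratic_dp(model$k_cct, model$area, mixture_density(gas), flow))
  if (!identical(model$gas_name, gas$name))
    stop("polynomial circuit model was fitted for gas '", model$gas_name,
         "', not '", gas$name, "'; refit or use an inertial-form model")
  sign(flow) * (model$c1 * abs(flow) + model$c2 * flow^2)
}

#' Inertial-collapse diagnostic for pressure-flow curves across gases
#'
#' If component losses are purely inertial, pressure drops for all gases
#' collapse onto a single line when plotted against `rho * Q^2`.  This
#' regresses the pooled points through the origin on `rho Q^2`, returning
#' the common slope (`beta = k / (2 A^2)`) and the scatter of the points
#' about the line, normalised by the largest measured drop.  Small scatter
#' indicates inertial dominance; a viscous (linear-in-Q) contribution
#' inflates it.
#'
#' @param curves a list of [pressure_flow_curve()] objects (>= 1; two or
#'   more gases make the diagnostic meaningful).
#' @return list with `slope` (Pa per kg m^-3 (m^3/s)^2), `scatter`
#'   (dimensionless RMS residual), and the pooled points.
#' @export
inertial_collapse_check <- function(curves) {
  if (inherits(curves, "pressure_flow_curve")) curves <- list(curves)
  if (!length(curves) || !all(vapply(curves, inherits, TRUE, "pressure_flow_curve")))
    stop("'curves' must be pressure_flow_curve objects")
  x <- unlist(lapply(curves, function(cv) mixture_density(cv$gas) * cv$flow^2))
  y <- unlist(lapply(curves, function(cv) cv$pressure_drop))
  keep <- x > 0
  if (sum(keep) < 2) stop("need at least 2 nonzero-flow points")
  slope <- sum(x[keep] * y[keep]) / sum(x[keep]^2)
  resid <- y - slope * x
  scatter <- sqrt(mean(resid^2)) / max(y)
  list(slope = slope, scatter = scatter,
       points = data.frame(rho_q2 = x, dp = y))
}
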