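# Factorial study sweeps over resistors, compliances, gases and breathing
# patterns, reproduction of the equivalent-resistance table, comparison of
# compartmental time constants with the ventilator-style RC, and synthetic
# trace fixtures for estimator validation.

#' Specification of the factorial study grid
#'
#' The bench design: the left branch resistor fixed (Rp5), the right branch
#' resistor swept over increasing obstructions, equal left/right
#' compliances swept over three values, two gases and two breathing
#' patterns.
#'
#' @param right_resistors named numeric vector of right-branch loss
#'   coefficients (default the Rp5/Rp20/Rp50 catalogue values).
#' @param left_resistor loss coefficient of the fixed left element
#'   (default Rp5, k = 3.3).
#' @param compliances chamber compliances, l/cm H2O (equal left/right).
#' @param gases list of [gas_mixture()] objects.
#' @param patterns list of [ventilator_settings()] objects.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(right_resistors = study_resistor_k(),
                       left_resistor = 3.3,
                       compliances = c(0.02, 0.05, 0.10),
                       gases = list(medical_air(), heliox()),
                       patterns = list(ventilator_settings(0.5, 12),
                                       ventilator_settings(1.0, 20))) {
  if (!length(right_resistors) || !length(compliances) ||
      !length(gases) || !length(patterns))
    stop("all sweep sets must be nonempty")
  if (is.null(names(right_resistors)))
    names(right_resistors) <- paste0("k", right_resistors)
  stopifnot(all(vapply(gases, inherits, TRUE, "gas_mixture")),
            all(vapply(patterns, inherits, TRUE, "ventilator_settings")))
  structure(list(right_resistors = right_resistors,
                 left_resistor = left_resistor,
                 compliances = compliances, gases = gases,
                 patterns = patterns),
            class = "sweep_spec")
}

#' Run the factorial study grid
#'
#' Simulates every grid point of a [sweep_spec()] to (attempted) steady
#' cycle and extracts, from the last simulated breath, the Brunner apparent
#' time constants of the right chamber, left chamber and whole lung, and
#' the ventilator-style RC from the total-flow trace.
#'
#' Per-point failures are recorded in the `error` column rather than
#' aborting the sweep.
#'
#' @param spec a [sweep_spec()].
#' @param circuit a [circuit_loss_model()] shared by all points.
#' @param area shared reference area, m^2.
#' @param k_fs branch flow-sensor loss coefficient.
#' @param dt time step, s.
#' @param n_breaths breaths simulated per chunk; simulation is extended in
#'   chunks (carrying volumes forward) until the steady-cycle criterion
#'   holds or `max_breaths` is reached.
#' @param max_breaths cap on total breaths per grid point.
#' @param allow_pendelluft passed to [lung_system()].
#' @param keep_iterations logical; if `TRUE`, attach the Brunner iteration
#'   histories as an attribute `"iterations"` (a list per row).
#' @return data.frame of class `sweep_result`, one row per grid point:
#'   resistor label and `k_right`, `compliance`, `gas`, `tidal_volume_l`,
#'   `rate`, `minute_ventilation_lpm`, `tau_right_s`, `tau_left_s`,
#'   `tau_whole_s`, `ventilator_rc_s`, `q_ep_right_lps`, `q_ep_whole_lps`,
#'   `v_etot_l`, `steady`, `error`.
#' @export
run_study_grid <- function(spec = sweep_spec(),
                           circuit = circuit_loss_model(),
                           area = default_resistor_area(),
                           k_fs = 1.2,
                           dt = 1e-3, n_breaths = 6, max_breaths = 24,
                           allow_pendelluft = TRUE,
                           keep_iterations = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- expand.grid(ir = seq_along(spec$right_resistors),
                      ic = seq_along(spec$compliances),
                      ig = seq_along(spec$gases),
                      ip = seq_along(spec$patterns))
  rows <- vector("list", nrow(grid))
  iters <- vector("list", nrow(grid))
  for (n in seq_len(nrow(grid))) {
    kR <- spec$right_resistors[grid$ir[n]]
    C <- spec$compliances[grid$ic[n]]
    gas <- spec$gases[[grid$ig[n]]]
    pat <- spec$patterns[[grid$ip[n]]]
    row <- data.frame(
      resistor = names(spec$right_resistors)[grid$ir[n]],
      k_right = unname(kR), k_left = spec$left_resistor,
      compliance = C, gas = gas$name,
      tidal_volume_l = pat$tidal_volume, rate = pat$rate,
      minute_ventilation_lpm = pat$tidal_volume * pat$rate,
      tau_right_s = NA_real_, tau_left_s = NA_real_, tau_whole_s = NA_real_,
      ventilator_rc_s = NA_real_,
      q_ep_right_lps = NA_real_, q_ep_whole_lps = NA_real_,
      v_etot_l = NA_real_, steady = NA, error = NA_character_,
      stringsAsFactors = FALSE)
    res <- tryCatch({
      sys <- lung_system(
        left = lung_chamber(C, parabolic_resistor(spec$left_resistor, area),
                            k_fs = k_fs),
        right = lung_chamber(C, parabolic_resistor(unname(kR), area),
                             k_fs = k_fs),
        gas = gas, circuit = circuit, area = area,
        allow_pendelluft = allow_pendelluft)
      sim <- simulate_lung(sys, pat, n_breaths = n_breaths, dt = dt)
      done <- n_breaths
      while (!sim$steady && done < max_breaths) {
        # carry volumes forward and extend until the cycle is steady
        nb <- sim$breaths[nrow(sim$breaths), ]
        sys$left$volume <- nb$v_end_exp_left_l
        sys$right$volume <- nb$v_end_exp_right_l
        sim <- simulate_lung(sys, pat, n_breaths = n_breaths, dt = dt)
        done <- done + n_breaths
      }
      tc <- breath_time_constants(sim)
      seg <- sim$trace[sim$trace$breath == max(sim$trace$breath) &
                         sim$trace$phase == "expiration", ]
      row$tau_right_s <- tc$right$tau
      row$tau_left_s <- tc$left$tau
      row$tau_whole_s <- tc$whole$tau
      row$ventilator_rc_s <- tc$ventilator_rc
      row$q_ep_right_lps <- max(seg$q_right_lps)
      row$q_ep_whole_lps <- max(seg$q_total_lps)
      row$v_etot_l <- sum(diff(seg$time_s) *
                            (seg$q_total_lps[-1] + seg$q_total_lps[-nrow(seg)]) / 2)
      row$steady <- sim$steady
      iters[[n]] <- list(right = tc$right, left = tc$left, whole = tc$whole)
      row
    }, error = function(e) { row$error <- conditionMessage(e); row })
    rows[[n]] <- res
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  if (keep_iterations) attr(out, "iterations") <- iters
  out
}

#' Correlate compartmental time constants with the ventilator RC
#'
#' Ordinary least-squares fits of each apparent-time-constant series
#' (right, left, whole lung) against the ventilator-style RC across the
#' grid, mirroring the bench comparison of compartmental values with the
#' ventilator's report.  The whole-lung and left (unobstructed) series
#' track the ventilator well; the obstructed right chamber does not.
#'
#' @param result a `sweep_result` from [run_study_grid()].
#' @return data.frame with one row per series (`right`, `left`, `whole`):
#'   `slope`, `intercept`, `r_squared`, `n`.
#' @export
compare_to_ventilator_rc <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  ok <- is.na(result$error) & is.finite(result$ventilator_rc_s)
  d <- result[ok, ]
  if (nrow(d) < 3) stop("need at least 3 successful grid points")
  if (stats::var(d$ventilator_rc_s) == 0)
    stop("degenerate fit: ventilator RC has zero variance")
  one <- function(y, label) {
    if (stats::var(y) == 0)
      stop("degenerate fit: '", label, "' series has zero variance")
    fit <- stats::lm(y ~ d$ventilator_rc_s)
    data.frame(series = label,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = summary(fit)$r.squared,
               n = nrow(d), stringsAsFactors = FALSE)
  }
  rbind(one(d$tau_right_s, "right"),
        one(d$tau_left_s, "left"),
        one(d$tau_whole_s, "whole"))
}

#' Regenerate the loss-coefficient / equivalent-resistance table
#'
#' Computes the equivalent linear resistance of each parabolic resistor for
#' each gas at each reference flow from the quadratic loss law with a
#' single calibrated entrance area, optionally rounded to one decimal as
#' printed in vendor/bench tables.
#'
#' @param gases list of [gas_mixture()] objects (default air and heliox).
#' @param flows_lpm reference flows, l/min (default 20 and 60).
#' @param resistors named numeric vector of loss coefficients.
#' @param area calibrated entrance area, m^2.
#' @param digits rounding for the `R_rounded` column (default 1).
#' @return data.frame: `resistor`, `k`, `flow_lpm`, `gas`, `R_cmh2o_s_l`,
#'   `R_rounded`.
#' @export
regenerate_table1 <- function(gases = list(medical_air(), heliox()),
                              flows_lpm = c(20, 60),
                              resistors = study_resistor_k(),
                              area = default_resistor_area(),
                              digits = 1) {
  rows <- list()
  for (rn in names(resistors)) for (f in flows_lpm) for (g in gases) {
    r <- parabolic_resistor(resistors[[rn]], area)
    R <- equivalent_linear_resistance(r, g, lpm_to_m3s(f))
    rows[[length(rows) + 1L]] <- data.frame(
      resistor = rn, k = resistors[[rn]], flow_lpm = f, gas = g$name,
      R_cmh2o_s_l = R, R_rounded = round(R, digits),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Synthetic flow-trace fixtures with known ground truth
#'
#' Generates reproducible expiratory traces for estimator validation:
#' `"mono"` a mono-exponential with known tau, `"bi"` a bi-exponential
#' (two compartments with distinct taus), `"simulated"` a right-chamber
#' trace from a full two-compartment simulation.  Optional additive
#' Gaussian noise is expressed as a fraction of the peak flow.
#'
#' @param kind one of `"mono"`, `"bi"`, `"simulated"`.
#' @param noise RMS noise as a fraction of peak flow (default 0).
#' @param seed integer seed fixing the noise realisation.
#' @param q_peak,tau,t_e,dt mono-exponential parameters (kind `"mono"`).
#' @param taus,weights bi-exponential parameters (kind `"bi"`): component
#'   time constants (s) and positive peak-flow weights.
#' @param sys,settings system and settings for kind `"simulated"`.
#' @return a [flow_trace()] with attribute `"truth"` describing the
#'   generator (tau(s), weights, or the simulation inputs).
#' @export
make_synthetic_trace <- function(kind = c("mono", "bi", "simulated"),
                                 noise = 0, seed = 1,
                                 q_peak = 1, tau = 0.5, t_e = 2, dt = 1e-3,
                                 taus = c(0.2, 0.8), weights = c(0.5, 0.5),
                                 sys = NULL, settings = NULL) {
  kind <- match.arg(kind)
  tr <- switch(kind,
    mono = {
      t0 <- mono_exponential_trace(q_peak, tau, t_e, dt)
      attr(t0, "truth") <- list(kind = "mono", tau = tau, q_peak = q_peak)
      t0
    },
    bi = {
      if (length(taus) != length(weights) || any(taus <= 0) || any(weights <= 0))
        stop("'taus' and 'weights' must be matching positive vectors")
      tt <- seq(0, t_e, by = dt)
      q <- colSums(weights * exp(-outer(1 / taus, tt)))
      t0 <- flow_trace(tt, q_peak * q / sum(weights))
      attr(t0, "truth") <- list(kind = "bi", taus = taus, weights = weights)
      t0
    },
    simulated = {
      if (is.null(sys) || is.null(settings))
        stop("kind 'simulated' needs 'sys' and 'settings'")
      sim <- simulate_lung(sys, settings, n_breaths = 4, dt = dt)
      seg <- sim$trace[sim$trace$breath == 4 & sim$trace$phase == "expiration", ]
      t0 <- flow_trace(seg$time_s - seg$time_s[1], pmax(seg$q_right_lps, 0))
      attr(t0, "truth") <- list(kind = "simulated", system = sys,
                                settings = settings)
      t0
    })
  if (noise > 0) {
    truth <- attr(tr, "truth")
    set.seed(seed)
    noisy <- tr$flows + stats::rnorm(length(tr$flows),
                                     sd = noise * max(tr$flows))
    tr <- flow_trace(tr$times, noisy)
    attr(tr, "truth") <- truth
  }
  tr
}
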