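# Quasi-steady simulation of the two-compartment test lung.
#
# During expiration each chamber obeys the energy balance from its interior
# to the atmosphere (reference pressure zero):
#
#   P_i = V_i / C_i = (k_i + k_fs)/2 * rho * (Q_i/A)|Q_i/A|
#                   + k_cct/2 * rho * ((Q_i+Q_j)/A)|(Q_i+Q_j)/A|
#
# i.e. elastic recoil balances the branch loss (resistor + flow sensor)
# plus the loss of the shared expiratory circuit at the combined flow.
# During inspiration the expiratory valve is closed; the ventilator's total
# flow splits between the branches so that both see a common Y-piece
# pressure.  Flows at each instant satisfy the static balance ("quasi-
# steady"): gas compressibility and component inertia are neglected.
#
# The coupled expiratory system is reduced to a single monotone scalar
# equation in the pressure P_c at the junction with the shared circuit:
# given P_c, each branch flow follows in closed form from
# Q_i = sign(P_i - P_c) * A_eff * sqrt(2|P_i - P_c| / rho), and P_c must
# equal the circuit loss at the combined flow.  The residual is strictly
# increasing in P_c, so the root is unique and bracketed by
# [0, max(P_L, P_R)].

#' Compliant test-lung chamber
#'
#' One compartment of the dual test lung: a linear compliance, the
#' parabolic resistor inserted in its branch, and the branch flow sensor's
#' loss coefficient.  Volume is measured above the relaxed volume, so the
#' recoil pressure is `V/C` and is zero at `V = 0`.
#'
#' @param compliance chamber compliance, l/cm H2O (study values 0.02, 0.05,
#'   0.10).
#' @param resistor a [parabolic_resistor()] in this branch.
#' @param k_fs dimensionless loss coefficient of the branch flow sensor,
#'   referenced to the system area.
#' @param volume initial volume above relaxed, l (>= 0).
#' @return an object of class `lung_chamber`.
#' @export
lung_chamber <- function(compliance, resistor, k_fs = 1.2, volume = 0) {
  if (compliance <= 0) stop("'compliance' must be positive (l/cm H2O)")
  if (volume < 0) stop("'volume' must be nonnegative (l)")
  stopifnot(inherits(resistor, "parabolic_resistor"))
  if (k_fs < 0) stop("'k_fs' must be >= 0")
  structure(list(compliance = compliance, resistor = resistor,
                 k_fs = k_fs, volume = volume),
            class = "lung_chamber")
}

#' Two-compartment lung system
#'
#' Couples two [lung_chamber()]s through a symmetric Y-piece to a shared
#' expiratory circuit.  Both chambers contain the same gas.
#'
#' @param left,right [lung_chamber()] objects.
#' @param gas a [gas_mixture()].
#' @param circuit a [circuit_loss_model()] for the shared expiratory path.
#' @param area shared reference cross-sectional area, m^2, to which the
#'   flow-sensor loss coefficients refer; defaults to the calibrated
#'   resistor entrance area.
#' @param allow_pendelluft logical; if `TRUE` (default) branch flows during
#'   expiration are signed, so a chamber may transiently receive gas expired
#'   by the other (pendelluft).  If `FALSE` branch outflows are clamped at
#'   zero and the chambers empty independently.
#' @return an object of class `lung_system`.
#' @examples
#' A <- default_resistor_area()
#' sys <- lung_system(
#'   left  = lung_chamber(0.05, parabolic_resistor(3.3, A)),
#'   right = lung_chamber(0.05, parabolic_resistor(132.9, A)),
#'   gas = heliox())
#' @export
lung_system <- function(left, right, gas,
                        circuit = circuit_loss_model(),
                        area = default_resistor_area(),
                        allow_pendelluft = TRUE) {
  stopifnot(inherits(left, "lung_chamber"), inherits(right, "lung_chamber"),
            inherits(gas, "gas_mixture"),
            inherits(circuit, "circuit_loss_model"))
  if (area <= 0) stop("'area' must be positive (m^2)")
  structure(list(left = left, right = right, gas = gas, circuit = circuit,
                 area = area, allow_pendelluft = isTRUE(allow_pendelluft),
                 time = 0),
            class = "lung_system")
}

#' @export
print.lung_system <- function(x, ...) {
  cat(sprintf("<lung_system> gas: %s (rho = %.4f kg/m^3)\n",
              x$gas$name, mixture_density(x$gas)))
  for (side in c("left", "right")) {
    ch <- x[[side]]
    cat(sprintf("  %-5s C = %g l/cmH2O, k = %g, k_fs = %g, V = %.4f l\n",
                side, ch$compliance, ch$resistor$k, ch$k_fs, ch$volume))
  }
  print(x$circuit)
  invisible(x)
}

# Internal SI parameterisation of a lung_system, precomputed once per run.
# K_eff[i] = (k_i / A_i^2 + k_fs / A^2): branch quadratic coefficient such
# that branch dp = rho/2 * K_eff * Q|Q|.
sys_pars <- function(sys) {
  rho <- mixture_density(sys$gas)
  keff <- function(ch)
    ch$resistor$k / ch$resistor$area^2 + ch$k_fs / sys$area^2
  list(
    rho = rho,
    C = c(cmh2o_to_pa(1)^-1 * 1e-3 * sys$left$compliance,
          cmh2o_to_pa(1)^-1 * 1e-3 * sys$right$compliance), # m^3/Pa
    K = c(keff(sys$left), keff(sys$right)),
    circuit = sys$circuit, gas = sys$gas,
    pendelluft = sys$allow_pendelluft
  )
}

# Branch flow (m^3/s) given recoil-minus-junction pressure difference d (Pa)
branch_flow <- function(d, rho, K) sign(d) * sqrt(2 * abs(d) / (rho * K))

# Expiratory flows in SI units; v is c(V_L, V_R) in m^3.  Returns flows out
# of each chamber (m^3/s, signed; negative = pendelluft inflow).
exp_flows_si <- function(p, v) {
  P <- v / p$C
  if (all(P <= 0)) return(c(0, 0))
  qi <- function(pc) {
    q <- branch_flow(P - pc, p$rho, p$K)
    if (!p$pendelluft) q <- pmax(q, 0)
    q
  }
  # residual: junction pressure minus circuit loss at the combined flow;
  # strictly increasing in pc, root unique in [0, max(P)]
  f <- function(pc) pc - circuit_pressure_drop(p$circuit, p$gas, sum(qi(pc)))
  if (f(0) >= 0) return(qi(0)) # circuit lossless at this state
  pmax_ <- max(P)
  root <- stats::uniroot(f, c(0, pmax_), tol = 1e-12 * max(pmax_, 1))$root
  qi(root)
}

# Inspiratory split in SI units: total ventilator flow q_tot (m^3/s, >= 0)
# divides so both branches see a common Y-piece pressure.  Returns flows
# into each chamber (signed; a negative value is pendelluft).
insp_split_si <- function(p, v, q_tot) {
  P <- v / p$C
  g <- function(ql)
    (P[1] + 0.5 * p$rho * p$K[1] * ql * abs(ql)) -
    (P[2] + 0.5 * p$rho * p$K[2] * (q_tot - ql) * abs(q_tot - ql))
  if (q_tot == 0 && P[1] == P[2]) return(c(0, 0))
  # g is strictly increasing in ql; bracket generously around [0, q_tot]
  span <- q_tot + sqrt(2 * (abs(P[1] - P[2]) + 1) / (p$rho * min(p$K)))
  lo <- -span; hi <- q_tot + span
  while (g(lo) > 0) lo <- lo - span
  while (g(hi) < 0) hi <- hi + span
  ql <- stats::uniroot(g, c(lo, hi), tol = 1e-14 * max(span, 1))$root
  c(ql, q_tot - ql)
}

#' Split the ventilator flow between the two branches
#'
#' Solves the inspiratory energy balance: the two branch flows sum to the
#' delivered total and both branches see the same Y-piece pressure, i.e.
#' `V_L/C_L + loss_L(Q_L) = V_R/C_R + loss_R(Q_R)`.  With signed quadratic
#' losses the balance is strictly monotone, so the split is unique.
#'
#' @param sys a [lung_system()].
#' @param q_tot total ventilator flow, l/s (>= 0).
#' @return named numeric: branch flows into each chamber, l/s.
#' @export
solve_inspiratory_split <- function(sys, q_tot) {
  stopifnot(inherits(sys, "lung_system"))
  if (q_tot < 0) stop("'q_tot' must be >= 0 (l/s)")
  p <- sys_pars(sys)
  v <- c(sys$left$volume, sys$right$volume) * 1e-3
  q <- insp_split_si(p, v, lps_to_m3s(q_tot))
  c(left = m3s_to_lps(q[1]), right = m3s_to_lps(q[2]))
}

#' Simultaneous expiratory branch flows
#'
#' Solves the coupled quasi-steady expiratory balance for both chambers:
#' each chamber's recoil pressure equals its branch loss plus the shared
#' circuit loss at the combined flow.  Flows are positive out of the
#' chamber; when `allow_pendelluft = TRUE` a chamber with low recoil may
#' show a negative (inflow) value while the other expires through it.
#'
#' @param sys a [lung_system()].
#' @return named numeric: branch flows out of each chamber, l/s.
#' @export
solve_expiratory_flows <- function(sys) {
  stopifnot(inherits(sys, "lung_system"))
  p <- sys_pars(sys)
  v <- c(sys$left$volume, sys$right$volume) * 1e-3
  q <- exp_flows_si(p, v)
  c(left = m3s_to_lps(q[1]), right = m3s_to_lps(q[2]))
}

#' Advance the system by one time step
#'
#' Determines the breath phase from the system's internal breath clock,
#' solves the appropriate quasi-steady flow problem, and updates chamber
#' volumes by explicit first-order quadrature `V <- V +/- Q dt` (clamped at
#' zero).  Phase transitions are instantaneous.
#'
#' @param sys a [lung_system()].
#' @param settings a [ventilator_settings()].
#' @param dt time step, s (> 0).
#' @return the updated `lung_system`, with an attribute `"step"` holding a
#'   list (`time`, `phase`, `q_left`, `q_right` in l/s at the start of the
#'   step).
#' @export
advance <- function(sys, settings, dt) {
  stopifnot(inherits(sys, "lung_system"),
            inherits(settings, "ventilator_settings"))
  if (dt <= 0) stop("'dt' must be positive")
  p <- sys_pars(sys)
  tm <- breath_timing(settings)
  tb <- sys$time %% tm$period
  v <- c(sys$left$volume, sys$right$volume) * 1e-3
  if (tb < tm$t_i) {
    phase <- "inspiration"
    q <- insp_split_si(p, v, lps_to_m3s(settings$tidal_volume / tm$t_i))
    v <- pmax(v + q * dt, 0)
  } else {
    phase <- "expiration"
    q <- exp_flows_si(p, v)
    v <- pmax(v - q * dt, 0)
  }
  sys$left$volume <- v[1] * 1e3
  sys$right$volume <- v[2] * 1e3
  sys$time <- sys$time + dt
  attr(sys, "step") <- list(time = sys$time - dt, phase = phase,
                            q_left = m3s_to_lps(q[1]),
                            q_right = m3s_to_lps(q[2]))
  sys
}

# Core stepping loop over whole breaths.  Works entirely in SI, records in
# clinical units.  Branch flows are recorded with the phase's natural sign:
# into the chamber during inspiration, out of it during expiration, so
# expiratory flow is positive within an expiration segment.
sim_core <- function(p, v0, settings, n_breaths, dt) {
  tm <- breath_timing(settings)
  n_i <- round(tm$t_i / dt)
  n_e <- round(tm$period / dt) - n_i
  n_step <- (n_i + n_e) * n_breaths
  time <- numeric(n_step); phase <- integer(n_step)
  ql <- numeric(n_step); qr <- numeric(n_step)
  vl <- numeric(n_step); vr <- numeric(n_step)
  breath <- integer(n_step)
  v <- v0
  q_insp <- lps_to_m3s(settings$tidal_volume / tm$t_i)
  end_exp <- matrix(NA_real_, n_breaths, 2)
  s <- 0L
  for (b in seq_len(n_breaths)) {
    t0 <- (b - 1) * tm$period
    for (i in seq_len(n_i)) {
      q <- insp_split_si(p, v, q_insp)
      s <- s + 1L
      time[s] <- t0 + (i - 1) * dt; phase[s] <- 1L; breath[s] <- b
      ql[s] <- q[1]; qr[s] <- q[2]; vl[s] <- v[1]; vr[s] <- v[2]
      v <- pmax(v + q * dt, 0)
    }
    for (i in seq_len(n_e)) {
      q <- exp_flows_si(p, v)
      s <- s + 1L
      time[s] <- t0 + tm$t_i + (i - 1) * dt; phase[s] <- 2L; breath[s] <- b
      ql[s] <- q[1]; qr[s] <- q[2]; vl[s] <- v[1]; vr[s] <- v[2]
      v <- pmax(v - q * dt, 0)
    }
    end_exp[b, ] <- v
  }
  list(time = time, phase = phase, breath = breath,
       ql = ql, qr = qr, vl = vl, vr = vr,
       end_exp = end_exp, v_final = v)
}

#' Simulate ventilation of the two-compartment system
#'
#' Runs `n_breaths` complete breaths from the system's current volumes
#' (default: both relaxed, `V = 0`) with explicit quasi-steady time
#' stepping, and reports whether a steady cycle was reached (end-expiratory
#' volume change below `steady_tol` per breath for both chambers).
#'
#' @param sys a [lung_system()].
#' @param settings a [ventilator_settings()].
#' @param n_breaths number of breaths to simulate (>= 1; default 6).
#' @param dt time step, s (default 0.001).
#' @param steady_tol steady-cycle tolerance on the per-breath change in
#'   end-expiratory volume, l (default 1e-4, i.e. 0.1 ml).
#' @return an object of class `lung_simulation`: a list with
#'   \describe{
#'     \item{trace}{data.frame with columns `time_s`, `breath`, `phase`,
#'       `q_left_lps`, `q_right_lps`, `q_total_lps`, `v_left_l`, `v_right_l`,
#'       `p_left_cmh2o`, `p_right_cmh2o`.  Branch flows carry the phase's
#'       natural sign (into the chamber during inspiration, out during
#'       expiration), so expiratory flow is positive within expiration.}
#'     \item{breaths}{per-breath end-expiratory volumes, l.}
#'     \item{steady}{logical, steady cycle reached.}
#'     \item{steady_breath}{first breath at which the steady criterion held
#'       (NA if never).}
#'     \item{system, settings, dt}{the inputs.}
#'   }
#' @export
simulate_lung <- function(sys, settings, n_breaths = 6, dt = 1e-3,
                          steady_tol = 1e-4) {
  stopifnot(inherits(sys, "lung_system"),
            inherits(settings, "ventilator_settings"))
  if (n_breaths < 1) stop("'n_breaths' must be >= 1")
  if (dt <= 0) stop("'dt' must be positive")
  p <- sys_pars(sys)
  v0 <- c(sys$left$volume, sys$right$volume) * 1e-3
  out <- sim_core(p, v0, settings, n_breaths, dt)

  trace <- data.frame(
    time_s = out$time,
    breath = out$breath,
    phase = c("inspiration", "expiration")[out$phase],
    q_left_lps = m3s_to_lps(out$ql),
    q_right_lps = m3s_to_lps(out$qr),
    q_total_lps = m3s_to_lps(out$ql + out$qr),
    v_left_l = out$vl * 1e3,
    v_right_l = out$vr * 1e3,
    p_left_cmh2o = pa_to_cmh2o(out$vl / p$C[1]),
    p_right_cmh2o = pa_to_cmh2o(out$vr / p$C[2])
  )
  ee <- out$end_exp * 1e3 # l
  dee <- if (n_breaths > 1) apply(abs(diff(ee)), 1, max) else numeric(0)
  steady_at <- which(dee < steady_tol)
  structure(list(trace = trace,
                 breaths = data.frame(breath = seq_len(n_breaths),
                                      v_end_exp_left_l = ee[, 1],
                                      v_end_exp_right_l = ee[, 2]),
                 steady = length(steady_at) > 0,
                 steady_breath = if (length(steady_at)) steady_at[1] + 1L else NA_integer_,
                 system = sys, settings = settings, dt = dt),
            class = "lung_simulation")
}

#' @export
print.lung_simulation <- function(x, ...) {
  nb <- max(x$breaths$breath)
  cat(sprintf("<lung_simulation> %d breaths @ dt = %g s; steady cycle: %s\n",
              nb, x$dt,
              if (x$steady) sprintf("yes (breath %d)", x$steady_breath) else "no"))
  ee <- x$breaths[nb, ]
  cat(sprintf("  end-expiratory volumes: L %.4f l, R %.4f l\n",
              ee$v_end_exp_left_l, ee$v_end_exp_right_l))
  invisible(x)
}

#' Simulate a single expiration from the current chamber volumes
#'
#' Runs only the expiratory solver for a duration `t_e` from the system's
#' current state (no inspiration).  Useful for comparing against the
#' closed-form single-chamber emptying solution.
#'
#' @param sys a [lung_system()] with the desired starting volumes.
#' @param t_e expiration duration, s.
#' @param dt time step, s.
#' @return data.frame with the same columns as the `trace` of
#'   [simulate_lung()] (phase all `"expiration"`, breath 1).
#' @export
simulate_expiration <- function(sys, t_e, dt = 1e-3) {
  stopifnot(inherits(sys, "lung_system"))
  p <- sys_pars(sys)
  v <- c(sys$left$volume, sys$right$volume) * 1e-3
  n <- round(t_e / dt)
  ql <- numeric(n); qr <- numeric(n); vl <- numeric(n); vr <- numeric(n)
  for (i in seq_len(n)) {
    q <- exp_flows_si(p, v)
    ql[i] <- q[1]; qr[i] <- q[2]; vl[i] <- v[1]; vr[i] <- v[2]
    v <- pmax(v - q * dt, 0)
  }
  data.frame(
    time_s = (seq_len(n) - 1) * dt, breath = 1L, phase = "expiration",
    q_left_lps = m3s_to_lps(ql), q_right_lps = m3s_to_lps(qr),
    q_total_lps = m3s_to_lps(ql + qr),
    v_left_l = vl * 1e3, v_right_l = vr * 1e3,
    p_left_cmh2o = pa_to_cmh2o(vl / p$C[1]),
    p_right_cmh2o = pa_to_cmh2o(vr / p$C[2])
  )
}

#' Closed-form emptying of a single chamber with quadratic drag
#'
#' For one compliant chamber venting through a purely quadratic loss
#' (total loss coefficient `k_tot` referenced to `area`), the quasi-steady
#' balance `V/C = (k_tot/2) rho (Q/A)^2` integrates in closed form:
#' `sqrt(V)` decreases linearly in time, the flow decays linearly,
#' `Q(t) = Q_0 (1 - t/t_empty)`, and the chamber empties completely at
#' `t_empty = sqrt(2 V_0 C rho k_tot) / A`.  Doubling the gas density (or
#' quadrupling the initial volume) thus increases the emptying time by
#' sqrt(2) (resp. a factor 2).  This is the analytic oracle against which
#' the time-stepping simulator is verified.
#'
#' @param compliance chamber compliance, l/cm H2O.
#' @param k_tot total dimensionless loss coefficient along the path.
#' @param area reference area, m^2.
#' @param gas a [gas_mixture()].
#' @param v0 initial volume above relaxed, l.
#' @param dt optional sampling step, s, for the returned trace.
#' @return list with `t_empty` (s), `peak_flow_lps`, `flow` (a function of
#'   time returning l/s) and, if `dt` is given, `trace` (data.frame
#'   `time_s`, `flow_lps`, `volume_l`).
#' @export
single_chamber_emptying <- function(compliance, k_tot, area, gas, v0,
                                    dt = NULL) {
  if (compliance <= 0 || k_tot <= 0 || area <= 0 || v0 < 0)
    stop("all parameters must be positive (v0 >= 0)")
  rho <- mixture_density(gas)
  C_si <- compliance * 1e-3 / PA_PER_CMH2O
  V0 <- v0 * 1e-3
  t_empty <- sqrt(2 * V0 * C_si * rho * k_tot) / area
  q0 <- area * sqrt(2 * V0 / (C_si * rho * k_tot)) # m^3/s
  flow <- function(t) m3s_to_lps(ifelse(t < t_empty, q0 * (1 - t / t_empty), 0))
  out <- list(t_empty = t_empty, peak_flow_lps = m3s_to_lps(q0), flow = flow)
  if (!is.null(dt)) {
    tt <- seq(0, max(t_empty * 1.05, dt), by = dt)
    vv <- ifelse(tt < t_empty, V0 * (1 - tt / t_empty)^2, 0)
    out$trace <- data.frame(time_s = tt, flow_lps = flow(tt),
                            volume_l = vv * 1e3)
  }
  out
}
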