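# Breath summaries and expiratory time constants.
#
# A linear single-compartment system empties mono-exponentially,
# Q_e(t) = Q_ep exp(-t/tau) with tau = R*C.  Real (and simulated) two-
# compartment, nonlinear-resistance emptying is not exponential; an
# *apparent* time constant is computed instead by the Brunner fixed-point
# iteration on the implicit relation obtained by evaluating the exhaled
# volume at end-expiration:
#
#   tau = (V_e,tot / Q_ep) * (1 - exp(-t_e/tau))^-1
#
# started from tau_0 = V_e,tot / Q_ep.  For non-exponential emptying the
# result is best read as an index of expiratory flow rather than a true
# decay constant.

#' Uniformly sampled flow-versus-time trace
#'
#' @param times sample times, s; strictly increasing, uniform spacing
#'   (within 1e-9 relative).
#' @param flows flow samples, l/s; expiratory flow positive within an
#'   expiration segment.
#' @param phase optional character vector of phase labels per sample.
#' @return an object of class `flow_trace`.
#' @export
flow_trace <- function(times, flows, phase = NULL) {
  if (length(times) != length(flows) || length(times) < 2)
    stop("'times' and 'flows' must have equal length >= 2")
  if (any(!is.finite(times)) || any(!is.finite(flows)))
    stop("'times' and 'flows' must be finite")
  dt <- diff(times)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt))
    stop("'times' must be strictly increasing on a uniform grid")
  structure(list(times = as.numeric(times), flows = as.numeric(flows),
                 phase = phase, dt = mean(dt)),
            class = "flow_trace")
}

#' Read/write flow traces as CSV
#'
#' CSV columns: `time_s`, `flow_lps`, optional `phase`; `#` comments
#' allowed.
#'
#' @param path file path.
#' @param trace a [flow_trace()] (for writing).
#' @return `read_flow_trace_csv` returns a [flow_trace()];
#'   `write_flow_trace_csv` returns `path` invisibly.
#' @export
read_flow_trace_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "flow_lps") %in% names(d)))
    stop("CSV must have columns 'time_s' and 'flow_lps'")
  flow_trace(d$time_s, d$flow_lps, phase = d[["phase"]])
}

#' @rdname read_flow_trace_csv
#' @export
write_flow_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "flow_trace"))
  d <- data.frame(time_s = trace$times, flow_lps = trace$flows)
  if (!is.null(trace$phase)) d$phase <- trace$phase
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Sample an ideal mono-exponential expiratory trace
#'
#' `Q_e(t) = Q_ep exp(-t/tau)` on `[0, t_e]`; the exhaled volume has the
#' closed form `V_e(t) = tau Q_ep (1 - exp(-t/tau))`.
#'
#' @param q_peak peak expiratory flow `Q_ep`, l/s.
#' @param tau time constant, s.
#' @param t_e exhalation time, s.
#' @param dt sampling step, s.
#' @return a [flow_trace()].
#' @export
mono_exponential_trace <- function(q_peak, tau, t_e, dt = 1e-3) {
  if (q_peak <= 0 || tau <= 0 || t_e <= 0 || dt <= 0)
    stop("all parameters must be positive")
  tt <- seq(0, t_e, by = dt)
  flow_trace(tt, q_peak * exp(-tt / tau))
}

#' Summarise one expiration of a flow trace
#'
#' Extracts the three inputs of the apparent-time-constant iteration from
#' an expiration window of a trace: peak expiratory flow `Q_ep` (max over
#' the window), total exhaled volume `V_e,tot` (trapezoidal integral) and
#' exhalation time `t_e` (window duration).
#'
#' For noisy recordings the raw sample maximum overestimates the peak (the
#' largest noise excursion rides on top of the signal), biasing the
#' apparent time constant low.  Setting `peak_window > 0` suppresses this:
#' the peak is located on a lightly smoothed copy of the trace and refined
#' by a local quadratic fit over a window of that width, whose maximum is
#' used as `Q_ep`.  Noiseless traces are unaffected to within the fit's
#' truncation error.
#'
#' @param trace a [flow_trace()] with expiratory flow positive in the
#'   window.
#' @param window optional numeric `c(t_start, t_end)` in trace time; default
#'   the whole trace.
#' @param peak_window width (s) of the local quadratic peak fit; 0
#'   (default) uses the raw sample maximum.
#' @return an object of class `breath_summary` with fields `v_etot` (l),
#'   `q_ep` (l/s) and `t_e` (s).
#' @export
extract_breath_summary <- function(trace, window = NULL, peak_window = 0) {
  stopifnot(inherits(trace, "flow_trace"))
  t <- trace$times; q <- trace$flows
  if (!is.null(window)) {
    if (window[1] < t[1] - 1e-12 || window[2] > t[length(t)] + 1e-12)
      stop("'window' must lie within the trace")
    keep <- t >= window[1] - 1e-12 & t <= window[2] + 1e-12
    t <- t[keep]; q <- q[keep]
  }
  if (length(t) < 2 || all(q == 0))
    stop("expiration window is empty or has all-zero flow")
  v <- sum(diff(t) * (q[-1] + q[-length(q)]) / 2)
  q_ep <- max(q)
  if (peak_window > 0) {
    dt <- t[2] - t[1]
    half <- max(1L, round(peak_window / (2 * dt)))
    if (length(q) >= 2 * half + 3) {
      sm <- stats::filter(q, rep(1 / (2 * half + 1), 2 * half + 1), sides = 2)
      sm[is.na(sm)] <- -Inf
      i0 <- which.max(sm)
      idx <- max(1L, i0 - 2L * half):min(length(q), i0 + 2L * half)
      tf <- t[idx] - t[i0]
      fit <- stats::lm(q[idx] ~ tf + I(tf^2))
      q_ep <- max(stats::predict(fit))
    }
  }
  breath_summary(v_etot = v, q_ep = q_ep, t_e = t[length(t)] - t[1])
}

#' @rdname extract_breath_summary
#' @param v_etot total exhaled volume, l.
#' @param q_ep peak expiratory flow, l/s.
#' @param t_e exhalation time, s.
#' @export
breath_summary <- function(v_etot, q_ep, t_e) {
  if (v_etot <= 0 || q_ep <= 0 || t_e <= 0)
    stop("'v_etot', 'q_ep' and 't_e' must all be positive")
  if (v_etot > q_ep * t_e * (1 + 1e-9))
    stop("inconsistent summary: exhaled volume exceeds q_ep * t_e")
  structure(list(v_etot = v_etot, q_ep = q_ep, t_e = t_e),
            class = "breath_summary")
}

#' Apparent expiratory time constant by fixed-point iteration
#'
#' Solves the implicit relation
#' `tau = (V_e,tot/Q_ep) / (1 - exp(-t_e/tau))` by the Brunner iteration:
#' `tau_0 = V_e,tot/Q_ep`, then
#' `tau_(k+1) = tau_0 / (1 - exp(-t_e/tau_k))`.  The iterates increase
#' monotonically from `tau_0` and are bounded, so the scheme converges for
#' any valid summary (`V_e,tot < Q_ep t_e`).  For a truncated
#' mono-exponential the fixed point is exactly the generating time
#' constant; for non-exponential emptying it is an index of expiratory
#' flow.
#'
#' @param summary a [breath_summary()].
#' @param tol relative convergence tolerance on successive iterates
#'   (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @return an object of class `time_constant_estimate`: list with `tau`
#'   (s), `tau0`, `iterations`, `history` (tau_0, tau_1, ...),
#'   `rel_change` (per-iteration relative change) and `converged`.
#' @export
apparent_time_constant <- function(summary, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(summary, "breath_summary"))
  tau0 <- summary$v_etot / summary$q_ep
  if (summary$v_etot >= summary$q_ep * summary$t_e)
    stop("no finite time constant: V_e,tot >= Q_ep * t_e ",
         "(flow did not decay within the window)")
  history <- tau0
  rel <- numeric(0)
  tau <- tau0
  converged <- FALSE
  for (k in seq_len(max_iter)) {
    tau_next <- tau0 / (1 - exp(-summary$t_e / tau))
    history <- c(history, tau_next)
    rel <- c(rel, abs(tau_next - tau) / tau)
    tau <- tau_next
    if (rel[k] < tol) { converged <- TRUE; break }
  }
  structure(list(tau = tau, tau0 = tau0, iterations = length(rel),
                 history = history, rel_change = rel, converged = converged,
                 summary = summary),
            class = "time_constant_estimate")
}

#' @export
print.time_constant_estimate <- function(x, ...) {
  cat(sprintf("<time_constant_estimate> tau = %.4f s (%d iterations, %s)\n",
              x$tau, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Ventilator-style expiratory RC from a flow trace
#'
#' Emulates the expiratory time constant reported by ventilators: the
#' ratio between expiratory tidal volume and expiratory flow, read at 75%
#' of the tidal volume.  The default reading takes the first instant at
#' which the volume *remaining* to be exhaled equals 75% of the expiratory
#' tidal volume and returns (remaining volume)/(flow) there, the reading
#' that recovers `tau` exactly for an ideal mono-exponential (where
#' remaining volume and flow stay strictly proportional).  Linear
#' interpolation is used between samples.
#'
#' Alternative readings of the ambiguous phrase are available:
#' `"exhaled25"` is identical to the default crossing but divides the full
#' tidal volume by the flow there; `"exhaled75"` reads the flow once 75% of
#' the tidal volume has been exhaled.
#'
#' @inheritParams extract_breath_summary
#' @param definition one of `"remaining75"` (default), `"exhaled25"`,
#'   `"exhaled75"`.
#' @return RC, s.
#' @export
ventilator_rc <- function(trace, window = NULL,
                          definition = c("remaining75", "exhaled25", "exhaled75")) {
  definition <- match.arg(definition)
  stopifnot(inherits(trace, "flow_trace"))
  t <- trace$times; q <- trace$flows
  if (!is.null(window)) {
    keep <- t >= window[1] - 1e-12 & t <= window[2] + 1e-12
    t <- t[keep]; q <- q[keep]
  }
  if (length(t) < 2) stop("window too short")
  dt <- diff(t)
  v <- c(0, cumsum(dt * (q[-1] + q[-length(q)]) / 2)) # exhaled volume
  v_tot <- v[length(v)]
  if (v_tot <= 0) stop("no exhaled volume in window")
  frac_exhaled <- switch(definition,
                         remaining75 = 0.25, exhaled25 = 0.25, exhaled75 = 0.75)
  target <- frac_exhaled * v_tot
  idx <- which(v >= target)[1]
  if (is.na(idx)) stop("volume target never crossed within the window")
  if (idx == 1L) idx <- 2L
  # linear interpolation of time, flow at the crossing
  w <- (target - v[idx - 1]) / (v[idx] - v[idx - 1])
  q_x <- q[idx - 1] + w * (q[idx] - q[idx - 1])
  if (q_x <= 0) stop("nonpositive flow at the volume target")
  switch(definition,
         remaining75 = (v_tot - target) / q_x,
         exhaled25 = v_tot / q_x,
         exhaled75 = v_tot / q_x)
}

#' Time constant of the linear single-compartment model
#'
#' `tau = R * C`: the product of resistance (cm H2O s/l) and compliance
#' (l/cm H2O); the units cancel to seconds.
#'
#' @param resistance cm H2O s/l (> 0).
#' @param compliance l/cm H2O (>= 0).
#' @return time constant, s.
#' @export
linear_model_time_constant <- function(resistance, compliance) {
  if (resistance <= 0 || compliance < 0)
    stop("'resistance' must be > 0 and 'compliance' >= 0")
  resistance * compliance
}

## ---- phase segmentation ---------------------------------------------------

#' Locate expiration windows in a simulated or annotated trace
#'
#' For traces carrying phase labels (as produced by [simulate_lung()]),
#' returns one `c(t_start, t_end)` window per expiration.  For unlabelled
#' traces, phases are segmented by zero crossings of the flow with a
#' hysteresis threshold (a fraction of the trace's peak |flow|) to reject
#' noise.
#'
#' @param trace a [flow_trace()].
#' @param hysteresis threshold as a fraction of peak absolute flow
#'   (default 0.01), used only when the trace has no phase labels.
#' @return list of numeric `c(t_start, t_end)` windows.
#' @export
expiration_windows <- function(trace, hysteresis = 0.01) {
  stopifnot(inherits(trace, "flow_trace"))
  t <- trace$times
  if (!is.null(trace$phase)) {
    is_exp <- trace$phase == "expiration"
  } else {
    thr <- hysteresis * max(abs(trace$flows))
    state <- 0L # 1 = expiration, -1 = inspiration
    is_exp <- logical(length(t))
    for (i in seq_along(t)) {
      f <- trace$flows[i]
      if (f > thr) state <- 1L else if (f < -thr) state <- -1L
      is_exp[i] <- state == 1L
    }
  }
  r <- rle(is_exp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > 1
  mapply(function(s, e) c(t[s], t[e]), starts[keep], ends[keep],
         SIMPLIFY = FALSE)
}

#' Per-branch expiratory time constants of one simulated breath
#'
#' Convenience wrapper: takes a [simulate_lung()] result, selects one
#' breath's expiration, and computes the Brunner apparent time constant for
#' the left chamber, right chamber, and whole lung (total flow), plus the
#' ventilator-style RC from the total-flow trace.
#'
#' @param sim a `lung_simulation`.
#' @param breath breath index (default: last simulated breath).
#' @param tol,max_iter passed to [apparent_time_constant()].
#' @return list with `left`, `right`, `whole` (each a
#'   `time_constant_estimate`) and `ventilator_rc` (s).
#' @export
breath_time_constants <- function(sim, breath = NULL, tol = 1e-6,
                                  max_iter = 100) {
  stopifnot(inherits(sim, "lung_simulation"))
  tr <- sim$trace
  if (is.null(breath)) breath <- max(tr$breath)
  seg <- tr[tr$breath == breath & tr$phase == "expiration", ]
  if (!nrow(seg)) stop("no expiration samples for breath ", breath)
  est <- function(q) {
    ft <- flow_trace(seg$time_s, pmax(q, 0))
    apparent_time_constant(extract_breath_summary(ft), tol, max_iter)
  }
  whole_tr <- flow_trace(seg$time_s, pmax(seg$q_total_lps, 0))
  list(left = est(seg$q_left_lps),
       right = est(seg$q_right_lps),
       whole = est(seg$q_total_lps),
       ventilator_rc = ventilator_rc(whole_tr))
}
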