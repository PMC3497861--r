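# Volume-control ventilation with constant (square-wave) inspiratory flow.

#' Ventilator settings for volume-control, constant-flow ventilation
#'
#' @param tidal_volume delivered tidal volume, l.
#' @param rate respiratory rate, breaths/min.
#' @param ie_ratio inspiratory:expiratory time ratio (dimensionless); the
#'   study patterns use 1/2.
#' @return an object of class `ventilator_settings`.
#' @examples
#' # the two study patterns: 6 and 20 l/min minute ventilation
#' ventilator_settings(0.5, 12)
#' ventilator_settings(1.0, 20)
#' @export
ventilator_settings <- function(tidal_volume, rate, ie_ratio = 0.5) {
  if (tidal_volume <= 0 || rate <= 0 || ie_ratio <= 0)
    stop("'tidal_volume', 'rate' and 'ie_ratio' must all be positive")
  structure(list(tidal_volume = tidal_volume, rate = rate,
                 ie_ratio = ie_ratio, waveform = "square"),
            class = "ventilator_settings")
}

#' @export
print.ventilator_settings <- function(x, ...) {
  tm <- breath_timing(x)
  cat(sprintf(
    "<ventilator_settings> VT = %g l @ %g/min (VE = %g l/min), I:E = %g\n",
    x$tidal_volume, x$rate, x$tidal_volume * x$rate, x$ie_ratio))
  cat(sprintf("  t_i = %.3f s, t_e = %.3f s, period = %.3f s, Q_insp = %.3f l/s\n",
              tm$t_i, tm$t_e, tm$period, x$tidal_volume / tm$t_i))
  invisible(x)
}

#' Breath phase timing
#'
#' Splits the breath period `60/rate` into inspiratory and expiratory
#' times according to the I:E ratio: `t_i = period * ie/(1 + ie)`.
#'
#' @param s a [ventilator_settings()].
#' @return list with `t_i`, `t_e` and `period`, all in seconds.
#' @export
breath_timing <- function(s) {
  stopifnot(inherits(s, "ventilator_settings"))
  period <- 60 / s$rate
  t_i <- period * s$ie_ratio / (1 + s$ie_ratio)
  list(t_i = t_i, t_e = period - t_i, period = period)
}

#' Total ventilator flow at a time within the breath
#'
#' Square-wave volume control: constant flow `VT / t_i` throughout
#' inspiration, zero during expiration.  Time is measured from the start of
#' inspiration.
#'
#' @param s a [ventilator_settings()].
#' @param t time since the start of the breath, s; must lie in
#'   `[0, period)`.
#' @return total flow delivered by the ventilator, l/s.
#' @export
inspiratory_flow <- function(s, t) {
  tm <- breath_timing(s)
  if (any(t < 0) || any(t >= tm$period))
    stop("'t' must lie within the breath: [0, ", format(tm$period), ")")
  ifelse(t < tm$t_i, s$tidal_volume / tm$t_i, 0)
}
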