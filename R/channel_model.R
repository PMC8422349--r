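#' Steady-state activation and inactivation
#'
#' Boltzmann steady-state curves of the two T-channel gates:
#' \deqn{m_\infty(V) = 1/(1 + e^{-(V - V_{1/2,act})/k_{act}})}
#' \deqn{h_\infty(V) = 1/(1 + e^{(V - V_{1/2,inact})/k_{inact}})}
#' `m_inf` is strictly increasing in voltage, `h_inf` strictly decreasing;
#' both map into (0, 1).
#'
#' @param v membrane voltage(s), mV; must be finite.
#' @param params a [gating_params()] object.
#' @return Gate occupancy fraction(s) in (0, 1).
#' @export
m_inf <- function(v, params) {
  stopifnot(inherits(params, "gating_params"))
  if (any(!is.finite(v))) stop("voltage must be finite", call. = FALSE)
  1 / (1 + exp(-(v - params$v_half_act) / params$k_act))
}

#' @rdname m_inf
#' @export
h_inf <- function(v, params) {
  stopifnot(inherits(params, "gating_params"))
  if (any(!is.finite(v))) stop("voltage must be finite", call. = FALSE)
  1 / (1 + exp((v - params$v_half_inact) / params$k_inact))
}

#' Voltage-dependent time constant from a tabulated curve
#'
#' Piecewise-linear interpolation of a (voltage, tau) table with constant
#' extrapolation beyond the table edges.  This is the package's stand-in for
#' parametric tau(V) functions: time constants are reported at discrete test
#' potentials, so the model consumes them as tables.
#'
#' @param v voltage(s), mV.
#' @param table two-column (voltage, tau) table, strictly increasing voltages.
#' @return Time constant(s), ms (always > 0).
#' @export
tau_gate <- function(v, table) {
  table <- check_tau_table(table, "table")
  stats::approx(table[, 1], table[, 2], xout = v, rule = 2)$y
}

#' Gate state of a two-gate channel
#'
#' @param m,h activation / inactivation gate occupancies in \[0, 1\].
#' @return An object of class `gate_state`.
#' @export
gate_state <- function(m, h) {
  stopifnot(is.numeric(m), is.numeric(h), length(m) == 1L, length(h) == 1L,
            m >= 0, m <= 1, h >= 0, h <= 1)
  structure(list(m = m, h = h), class = "gate_state")
}

#' Relax the gates toward steady state at a fixed voltage
#'
#' Each gate relaxes first-order toward its steady state using the update
#' \eqn{x \leftarrow x_\infty + (x - x_\infty) e^{-dt/\tau_x(V)}}, which is
#' the exact solution at constant voltage (so n steps of dt/n equal one step
#' of dt to machine precision).
#'
#' @param state a [gate_state()].
#' @param v voltage, mV.
#' @param dt time step, ms (> 0).
#' @param params a [gating_params()] object.
#' @return The updated `gate_state`.
#' @export
step_gates <- function(state, v, dt, params) {
  stopifnot(inherits(state, "gate_state"), inherits(params, "gating_params"),
            is.finite(v), dt > 0)
  minf <- m_inf(v, params)
  hinf <- h_inf(v, params)
  tm <- tau_gate(v, m_tau_table(params))
  th <- tau_gate(v, params$tau_inact_table)
  gate_state(m = minf + (state$m - minf) * exp(-dt / tm),
             h = hinf + (state$h - hinf) * exp(-dt / th))
}

#' Instantaneous channel current
#'
#' Ohmic current through the open fraction of channels,
#' \eqn{I = \bar g\, m^{p}\, h\, (V - E_{rev})}: inward (negative) below the
#' reversal potential when the gates are open.  Units follow `g_max`: nS
#' gives pA (whole-cell mode), mS/cm^2 gives uA/cm^2 (density mode).
#'
#' @param v voltage, mV.
#' @param state a [gate_state()].
#' @param params a [gating_params()] object.
#' @return Current in pA (whole-cell) or uA/cm^2 (density).
#' @export
channel_current <- function(v, state, params) {
  stopifnot(inherits(state, "gate_state"), inherits(params, "gating_params"))
  params$g_max * state$m^params$p_act * state$h * (v - params$e_rev)
}

#' Window-current curve
#'
#' The steady-state open fraction \eqn{w(V) = m_\infty(V)^{p} h_\infty(V)}:
#' the overlap between the activation and inactivation curves.  Channels in
#' this voltage range are persistently open, producing the sustained
#' "window" current that dominates excitability near rest.
#'
#' @param params a [gating_params()] object.
#' @param v_grid voltage grid, mV; must span at least \[-100, 0\] mV.  A
#'   spacing above 1 mV triggers a warning (the peak is located by grid
#'   argmax).
#' @return An object of class `window_curve` with fields `voltages`,
#'   `window`, `peak_voltage` (argmax; ties broken toward the most negative
#'   voltage), `peak_value` and trapezoid `area` (fraction x mV).
#' @export
window_curve <- function(params, v_grid = seq(-100, 0, by = 0.1)) {
  stopifnot(inherits(params, "gating_params"))
  v_grid <- sort(v_grid)
  if (min(v_grid) > -100 || max(v_grid) < 0) {
    stop("v_grid must span at least [-100, 0] mV", call. = FALSE)
  }
  if (max(diff(v_grid)) > 1 + 1e-9) {
    warning("v_grid spacing above 1 mV: window peak location will be coarse")
  }
  w <- m_inf(v_grid, params)^params$p_act * h_inf(v_grid, params)
  i_pk <- which.max(w)  # which.max returns the first (most negative) maximum
  area <- sum(diff(v_grid) * (w[-1] + w[-length(w)]) / 2)
  structure(list(voltages = v_grid, window = w,
                 peak_voltage = v_grid[i_pk], peak_value = w[i_pk],
                 area = area, variant = params$name),
            class = "window_curve")
}

#' @export
print.window_curve <- function(x, ...) {
  cat(sprintf("<window_curve> %s: peak %.4g at %.1f mV, area %.3g fraction*mV\n",
              x$variant, x$peak_value, x$peak_voltage, x$area))
  invisible(x)
}
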