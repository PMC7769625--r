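#' Stimulation protocols
#'
#' Protocol constructors for [csc_simulate()]:
#' * `protocol_constant()`: the constant `I_app` carried by the parameter set
#'   (0 by default — the cell is spontaneously active).
#' * `protocol_step()`: a bias current `I_bias` switching to `I_test` at
#'   `t_step` ms.
#' * `protocol_hold_release()`: the state is initialized at the conditional
#'   steady state of the voltage-clamped system at `V_hold` and released at
#'   t = 0 (a deterministic stand-in for a voltage-clamp episode).
#' * `protocol_synaptic_pair()`: an inhibitory followed by an excitatory
#'   alpha-function conductance input, the excitation lagging by `lag` ms.
#'
#' @param I_bias,I_test current densities (uA/cm^2).
#' @param t_step step onset (ms).
#' @param V_hold holding potential (mV), within (-120, 0).
#' @param g_inh,g_exc peak synaptic conductances (uS/cm^2).
#' @param E_inh,E_exc synaptic reversal potentials (mV).
#' @param tau_inh,tau_exc alpha-function time constants (ms).
#' @param onset onset of the inhibitory input (ms).
#' @param lag inhibition-to-excitation onset delay (ms).
#' @return a `csc_protocol` object.
#' @name protocols
NULL

#' @rdname protocols
#' @export
protocol_constant <- function() {
  structure(list(kind = "constant"), class = "csc_protocol")
}

#' @rdname protocols
#' @export
protocol_step <- function(I_bias, I_test, t_step) {
  stopifnot(is.numeric(I_bias), is.numeric(I_test), t_step >= 0)
  structure(list(kind = "step", I_bias = I_bias, I_test = I_test,
                 t_step = t_step), class = "csc_protocol")
}

#' @rdname protocols
#' @export
protocol_hold_release <- function(V_hold) {
  stopifnot(V_hold > -120, V_hold < 0)
  structure(list(kind = "hold_release", V_hold = V_hold),
            class = "csc_protocol")
}

#' @rdname protocols
#' @export
protocol_synaptic_pair <- function(g_inh, g_exc, E_inh = -80, E_exc = 0,
                                   tau_inh = 5, tau_exc = 1,
                                   onset = 50, lag = 5) {
  stopifnot(g_inh >= 0, g_exc >= 0, tau_inh > 0, tau_exc > 0)
  structure(list(kind = "synaptic_pair", g_inh = g_inh, g_exc = g_exc,
                 E_inh = E_inh, E_exc = E_exc, tau_inh = tau_inh,
                 tau_exc = tau_exc, onset_inh = onset,
                 onset_exc = onset + lag), class = "csc_protocol")
}

#' Alpha-function synaptic conductance
#'
#' `g(t) = peak * ((t - onset)/tau) * exp(1 - (t - onset)/tau)` for
#' `t >= onset`, zero before; the maximum equals `peak` at `t = onset + tau`
#' and the integral over the pulse is `peak * tau * e`.
#'
#' @param t time (ms); vectorized.
#' @param peak peak conductance (uS/cm^2).
#' @param tau time constant (ms), > 0.
#' @param onset onset time (ms).
#' @return conductance (uS/cm^2).
#' @export
synaptic_conductance <- function(t, peak, tau, onset = 0) {
  stopifnot(tau > 0)
  s <- (t - onset) / tau
  ifelse(t < onset, 0, peak * s * exp(1 - s))
}

# encode a protocol into the tail of the C parameter vector
protocol_vector <- function(protocol) {
  kind <- if (is.null(protocol)) "constant" else protocol$kind
  v <- numeric(12)
  v[1] <- switch(kind, constant = 0, hold_release = 0, step = 1,
                 synaptic_pair = 2)
  if (kind == "step") {
    v[2] <- protocol$I_bias; v[3] <- protocol$I_test; v[4] <- protocol$t_step
  } else if (kind == "synaptic_pair") {
    v[5] <- protocol$g_inh; v[6] <- protocol$g_exc
    v[7] <- protocol$E_inh; v[8] <- protocol$E_exc
    v[9] <- protocol$tau_inh; v[10] <- protocol$tau_exc
    v[11] <- protocol$onset_inh; v[12] <- protocol$onset_exc
  }
  v
}

default_init_state <- function(params, protocol = NULL) {
  if (!is.null(protocol) && protocol$kind == "hold_release") {
    equilibrate_at_hold(params, protocol$V_hold)
  } else {
    equilibrate_at_hold(params, -70)
  }
}

#' Integrate the full model
#'
#' Stiff integration (lsoda, compiled right-hand side) of the eight-variable
#' model under a stimulation protocol, with dense output resolving action
#' potential upstrokes. Deterministic: identical inputs give identical
#' output.
#'
#' @param params a [csc_params()] set.
#' @param duration simulated time (ms), > 0.
#' @param protocol a protocol (see [protocols]); `NULL` = constant `I_app`.
#' @param init initial state (see [csc_state()]); defaults to the conditional
#'   steady state at -70 mV (or at `V_hold` for hold-and-release).
#' @param dt output sampling interval (ms).
#' @param rtol,atol solver tolerances.
#' @return a `csc_trajectory`: a tibble with columns `t, V, h, n, nA, hA, hT,
#'   mHVA, Ca` and the parameters/protocol/solver settings as attributes.
#' @examples
#' \donttest{
#' traj <- csc_simulate(csc_params("post"), duration = 1000)
#' }
#' @export
csc_simulate <- function(params, duration, protocol = NULL, init = NULL,
                         dt = 0.02, rtol = 1e-8, atol = 1e-8) {
  stopifnot(duration > 0)
  if (is.null(init)) init <- default_init_state(params, protocol)
  stopifnot(length(init) == 8)
  names(init) <- state_names()
  times <- seq(0, duration, by = dt)
  pv <- .csc_param_vector(params, protocol)
  out <- deSolve::ode(y = init, times = times, func = "csc_derivs",
                      parms = pv, dllname = "cscburst",
                      initfunc = "csc_initmod", method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 50000)
  finish_trajectory(out, params, protocol,
                    list(rtol = rtol, atol = atol, dt = dt),
                    state_names(), "csc_trajectory")
}

#' Integrate the fast subsystem at frozen slow variables
#'
#' @inheritParams csc_simulate
#' @param hA,Ca frozen slow-variable values.
#' @param init initial fast state (`V, h, n, nA, hT, mHVA`); defaults to the
#'   clamped steady state at -70 mV.
#' @return a `csc_fast_trajectory` tibble with columns `t, V, h, n, nA, hT,
#'   mHVA`.
#' @export
fast_simulate <- function(params, hA, Ca, duration, init = NULL,
                          dt = 0.02, rtol = 1e-8, atol = 1e-8) {
  stopifnot(duration > 0, hA >= 0, hA <= 1, Ca >= 0)
  if (is.null(init)) {
    init <- default_init_state(params)[fast_state_names()]
  }
  stopifnot(length(init) == 6)
  names(init) <- fast_state_names()
  times <- seq(0, duration, by = dt)
  pv <- .csc_param_vector(params, NULL, hA = hA, Ca = Ca)
  out <- deSolve::ode(y = init, times = times, func = "csc_fast_derivs",
                      parms = pv, dllname = "cscburst",
                      initfunc = "csc_initmod", method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 50000)
  traj <- finish_trajectory(out, params, NULL,
                            list(rtol = rtol, atol = atol, dt = dt),
                            fast_state_names(), "csc_fast_trajectory")
  attr(traj, "frozen") <- c(hA = hA, Ca = Ca)
  traj
}

finish_trajectory <- function(out, params, protocol, solver, cols, cls) {
  m <- unclass(out)
  if (any(!is.finite(m))) {
    bad <- which(rowSums(!is.finite(m)) > 0)[1]
    stop(sprintf("integration produced non-finite state at t = %.3f ms",
                 m[bad, 1]))
  }
  df <- tibble::as_tibble(as.data.frame(m))
  names(df) <- c("t", cols)
  attr(df, "params") <- params
  attr(df, "protocol") <- protocol
  attr(df, "solver") <- solver
  class(df) <- c(cls, class(df))
  df
}

#' Post-transient analysis window of a trajectory
#'
#' Discards an initial transient (25% of the trace, at least 500 ms when the
#' trace allows it) and keeps the last 80% of the remainder, the convention
#' used by all feature extraction in the package.
#'
#' @param traj a trajectory tibble with a `t` column.
#' @param discard transient to discard (ms); `NULL` for the default rule.
#' @return the windowed trajectory (attributes preserved).
#' @export
analysis_window <- function(traj, discard = NULL) {
  dur <- max(traj$t) - min(traj$t)
  if (is.null(discard)) discard <- max(0.25 * dur, min(500, 0.5 * dur))
  t0 <- min(traj$t) + discard
  t0 <- t0 + 0.2 * (max(traj$t) - t0)
  keep <- traj$t >= t0
  out <- traj[keep, ]
  for (a in c("params", "protocol", "solver", "frozen"))
    attr(out, a) <- attr(traj, a)
  class(out) <- class(traj)
  out
}

traj_params <- function(traj) attr(traj, "params")
traj_protocol <- function(traj) attr(traj, "protocol")
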