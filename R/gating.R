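#' Steady-state gating sigmoid
#'
#' Boltzmann steady state `1 / (1 + exp(-(V - v_x)/s_x))` shared by every
#' voltage-dependent gate of the model. `s_x > 0` gives an activation curve
#' (increasing in V), `s_x < 0` an inactivation curve.
#'
#' @param V membrane potential (mV); vectorized.
#' @param v_x half-(in)activation potential (mV).
#' @param s_x slope factor (mV); must be non-zero.
#' @return gating fraction in (0, 1).
#' @export
gate_steady_state <- function(V, v_x, s_x) {
  if (any(s_x == 0)) stop("slope factor s_x must be non-zero")
  1 / (1 + exp(-(V - v_x) / s_x))
}

# derivative of the sigmoid w.r.t. V
gate_steady_state_dV <- function(V, v_x, s_x) {
  x <- gate_steady_state(V, v_x, s_x)
  x * (1 - x) / s_x
}

#' Voltage-dependent time constant of Na inactivation
#'
#' Lorentzian profile `y0 + (2 A / pi) * w / (4 (V - Vc)^2 + w^2)`: peaked at
#' `V = Vc`, symmetric, approaching the floor `y0` far from the peak.
#'
#' @param V membrane potential (mV); vectorized.
#' @param params a [csc_params()] set supplying `y0` (ms), `A` (ms.mV),
#'   `w` (mV) and `Vc` (mV).
#' @return time constant (ms).
#' @export
tau_h <- function(V, params = csc_params()) {
  d <- V - params$Vc
  params$y0 + (2 * params$A / pi) * params$w / (4 * d^2 + params$w^2)
}

tau_h_dV <- function(V, params) {
  d <- V - params$Vc
  -(2 * params$A / pi) * params$w * 8 * d / (4 * d^2 + params$w^2)^2
}

#' Voltage-dependent time constant of delayed-rectifier K activation
#'
#' `tau_n(V) = 6 / (1 + exp((V + 23)/15))` ms: monotone decreasing from 6 ms
#' at hyperpolarized potentials towards 0 at depolarized ones.
#'
#' @param V membrane potential (mV); vectorized.
#' @return time constant (ms), in (0, 6).
#' @export
tau_n <- function(V) {
  6 / (1 + exp((V + 23) / 15))
}

tau_n_dV <- function(V) {
  e <- exp((V + 23) / 15)
  -6 * e / (15 * (1 + e)^2)
}
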