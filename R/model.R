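#' Construct a model state
#'
#' The eight dynamic variables of the full system: membrane potential `V`,
#' the stored gating fractions `h, n, nA, hA, hT, mHVA`, and cytosolic
#' calcium `Ca` (uM). The Na and T-type activation gates are instantaneous
#' (evaluated from V), so they are never stored.
#'
#' @param V mV; `h,n,nA,hA,hT,mHVA` gating fractions in `[0,1]`; `Ca` uM.
#' @return a named numeric vector of length 8.
#' @export
csc_state <- function(V, h, n, nA, hA, hT, mHVA, Ca) {
  st <- c(V = V, h = h, n = n, nA = nA, hA = hA, hT = hT, mHVA = mHVA, Ca = Ca)
  gates <- st[2:7]
  if (any(!is.finite(st))) stop("non-finite state")
  if (any(gates < 0 | gates > 1)) stop("gating fractions must lie in [0, 1]")
  st
}

#' State with all gates at their voltage steady state
#'
#' All stored gates at `x_inf(V)` and calcium at its balance value
#' `-alpha (I_T + I_HVA) / k` evaluated at `V` (floored at 0). This is the
#' conditional steady state of the model when `V` is clamped, used to
#' initialize hold-and-release protocols.
#'
#' @param params a [csc_params()] set.
#' @param V holding potential (mV).
#' @return a state vector (see [csc_state()]).
#' @export
equilibrate_at_hold <- function(params, V) {
  p <- params
  st <- c(V = V,
          h = gate_steady_state(V, p$v_h, p$s_h),
          n = gate_steady_state(V, p$v_n, p$s_n),
          nA = gate_steady_state(V, p$v_nA, p$s_nA),
          hA = gate_steady_state(V, p$v_hA, p$s_hA),
          hT = gate_steady_state(V, p$v_hT, p$s_hT),
          mHVA = gate_steady_state(V, p$v_mHVA, p$s_mHVA),
          Ca = 0)
  I <- ionic_currents(st, p)
  st["Ca"] <- max(0, -p$alpha * (I[["I_T"]] + I[["I_HVA"]]) / p$k)
  st
}

#' Ionic current breakdown at a state
#'
#' Evaluates the seven current densities of the model. Each current vanishes
#' at its reversal potential. The Ca-activated K current is gated by a
#' fifth-order Hill function of cytosolic calcium.
#'
#' @param state a state vector (see [csc_state()]).
#' @param params a [csc_params()] set.
#' @return named numeric vector `I_Na, I_K, I_L, I_A, I_T, I_HVA, I_KCa`
#'   (uA/cm^2).
#' @export
ionic_currents <- function(state, params) {
  p <- params
  V <- state[["V"]]
  m_inf <- gate_steady_state(V, p$v_m, p$s_m)
  mT_inf <- gate_steady_state(V, p$v_mT, p$s_mT)
  Ca <- state[["Ca"]]
  hill <- Ca^5 / (p$k_Ca^5 + Ca^5)
  c(I_Na = p$g_Na * m_inf^3 * state[["h"]] * (V - p$E_Na),
    I_K = p$g_K * state[["n"]]^4 * (V - p$E_K),
    I_L = p$g_L * (V - p$E_L),
    I_A = p$g_A * state[["nA"]] * state[["hA"]] * (V - p$E_K),
    I_T = p$g_T * mT_inf * state[["hT"]] * (V - p$E_Ca),
    I_HVA = p$g_HVA * state[["mHVA"]] * (V - p$E_Ca),
    I_KCa = p$g_KCa * hill * (V - p$E_K))
}

#' Right-hand side of the full system
#'
#' Pure-R reference implementation of the model's vector field (the compiled
#' version in `src/` is used for integration). Current balance on `V`,
#' first-order relaxation of each stored gate to its voltage steady state,
#' and calcium balance `dCa/dt = -eps (alpha (I_T + I_HVA) + k Ca)` combining
#' influx through the two Ca currents with linear extrusion.
#'
#' @param state a state vector (see [csc_state()]).
#' @param params a [csc_params()] set.
#' @param t time (ms), used only by time-dependent protocols.
#' @param protocol a protocol (see [protocol_constant()]); `NULL` means the
#'   constant `I_app` in `params`.
#' @return named derivative vector (length 8).
#' @export
csc_rhs <- function(state, params, t = 0, protocol = NULL) {
  if (any(!is.finite(state))) stop("non-finite state passed to csc_rhs")
  p <- params
  V <- state[["V"]]
  I <- ionic_currents(state, p)
  Iapp <- applied_current(t, V, p, protocol)
  c(V = (Iapp - sum(I)) / p$C,
    h = (gate_steady_state(V, p$v_h, p$s_h) - state[["h"]]) / tau_h(V, p),
    n = (gate_steady_state(V, p$v_n, p$s_n) - state[["n"]]) / tau_n(V),
    nA = (gate_steady_state(V, p$v_nA, p$s_nA) - state[["nA"]]) / p$tau_nA,
    hA = (gate_steady_state(V, p$v_hA, p$s_hA) - state[["hA"]]) / p$tau_hA,
    hT = (gate_steady_state(V, p$v_hT, p$s_hT) - state[["hT"]]) / p$tau_hT,
    mHVA = (gate_steady_state(V, p$v_mHVA, p$s_mHVA) - state[["mHVA"]]) /
      p$tau_mHVA,
    Ca = -p$eps * (p$alpha * (I[["I_T"]] + I[["I_HVA"]]) +
                     p$k * state[["Ca"]]))
}

#' Right-hand side of the fast subsystem
#'
#' The six fast variables `V, h, n, nA, hT, mHVA` with the two slowest
#' variables `hA` and `Ca` frozen as parameters — the object of slow-fast
#' dissection of the bursting dynamics.
#'
#' @param fast_state named vector `V, h, n, nA, hT, mHVA`.
#' @param hA,Ca frozen slow values (`hA` in `[0,1]`, `Ca >= 0` uM).
#' @param params a [csc_params()] set.
#' @return named derivative vector (length 6).
#' @export
fast_rhs <- function(fast_state, hA, Ca, params) {
  full <- c(fast_state[1:4], hA = hA, fast_state[5:6], Ca = Ca)
  names(full) <- state_names()
  d <- csc_rhs(full, params)
  d[fast_state_names()]
}

# applied current as a function of time (R mirror of the C implementation)
applied_current <- function(t, V, params, protocol = NULL) {
  if (is.null(protocol) || protocol$kind %in% c("constant", "hold_release"))
    return(params$I_app)
  if (protocol$kind == "step")
    return(ifelse(t < protocol$t_step, protocol$I_bias, protocol$I_test))
  # synaptic_pair
  gi <- synaptic_conductance(t, protocol$g_inh, protocol$tau_inh,
                             protocol$onset_inh)
  ge <- synaptic_conductance(t, protocol$g_exc, protocol$tau_exc,
                             protocol$onset_exc)
  params$I_app - gi * (V - protocol$E_inh) - ge * (V - protocol$E_exc)
}

#' Analytic Jacobian of the full system
#'
#' Entry-wise derivative matrix of [csc_rhs()] with respect to the state,
#' used for stability certificates along continuation branches.
#'
#' @inheritParams csc_rhs
#' @return an 8 x 8 matrix with dimnames the state names.
#' @export
csc_jacobian <- function(state, params, t = 0, protocol = NULL) {
  p <- params
  V <- state[["V"]]
  h <- state[["h"]]; n <- state[["n"]]; nA <- state[["nA"]]
  hA <- state[["hA"]]; hT <- state[["hT"]]; mHVA <- state[["mHVA"]]
  Ca <- state[["Ca"]]

  m_inf <- gate_steady_state(V, p$v_m, p$s_m)
  dm_inf <- gate_steady_state_dV(V, p$v_m, p$s_m)
  mT_inf <- gate_steady_state(V, p$v_mT, p$s_mT)
  dmT_inf <- gate_steady_state_dV(V, p$v_mT, p$s_mT)
  hill <- Ca^5 / (p$k_Ca^5 + Ca^5)
  dhill <- 5 * p$k_Ca^5 * Ca^4 / (p$k_Ca^5 + Ca^5)^2

  # d(sum I)/dV and cross derivatives
  dI_dV <- p$g_Na * (3 * m_inf^2 * dm_inf * h * (V - p$E_Na) + m_inf^3 * h) +
    p$g_K * n^4 + p$g_L + p$g_A * nA * hA +
    p$g_T * (dmT_inf * hT * (V - p$E_Ca) + mT_inf * hT) +
    p$g_HVA * mHVA + p$g_KCa * hill
  # synaptic protocols add conductance terms on V
  if (!is.null(protocol) && protocol$kind == "synaptic_pair") {
    dI_dV <- dI_dV +
      protocol$g_inh * synaptic_conductance(t, 1, protocol$tau_inh,
                                            protocol$onset_inh) +
      protocol$g_exc * synaptic_conductance(t, 1, protocol$tau_exc,
                                            protocol$onset_exc)
  }

  J <- matrix(0, 8, 8, dimnames = list(state_names(), state_names()))
  J["V", "V"] <- -dI_dV / p$C
  J["V", "h"] <- -p$g_Na * m_inf^3 * (V - p$E_Na) / p$C
  J["V", "n"] <- -4 * p$g_K * n^3 * (V - p$E_K) / p$C
  J["V", "nA"] <- -p$g_A * hA * (V - p$E_K) / p$C
  J["V", "hA"] <- -p$g_A * nA * (V - p$E_K) / p$C
  J["V", "hT"] <- -p$g_T * mT_inf * (V - p$E_Ca) / p$C
  J["V", "mHVA"] <- -p$g_HVA * (V - p$E_Ca) / p$C
  J["V", "Ca"] <- -p$g_KCa * dhill * (V - p$E_K) / p$C

  th <- tau_h(V, p)
  J["h", "V"] <- gate_steady_state_dV(V, p$v_h, p$s_h) / th -
    (gate_steady_state(V, p$v_h, p$s_h) - h) * tau_h_dV(V, p) / th^2
  J["h", "h"] <- -1 / th

  tn <- tau_n(V)
  J["n", "V"] <- gate_steady_state_dV(V, p$v_n, p$s_n) / tn -
    (gate_steady_state(V, p$v_n, p$s_n) - n) * tau_n_dV(V) / tn^2
  J["n", "n"] <- -1 / tn

  J["nA", "V"] <- gate_steady_state_dV(V, p$v_nA, p$s_nA) / p$tau_nA
  J["nA", "nA"] <- -1 / p$tau_nA
  J["hA", "V"] <- gate_steady_state_dV(V, p$v_hA, p$s_hA) / p$tau_hA
  J["hA", "hA"] <- -1 / p$tau_hA
  J["hT", "V"] <- gate_steady_state_dV(V, p$v_hT, p$s_hT) / p$tau_hT
  J["hT", "hT"] <- -1 / p$tau_hT
  J["mHVA", "V"] <- gate_steady_state_dV(V, p$v_mHVA, p$s_mHVA) / p$tau_mHVA
  J["mHVA", "mHVA"] <- -1 / p$tau_mHVA

  dIT_dV <- p$g_T * (dmT_inf * hT * (V - p$E_Ca) + mT_inf * hT)
  dIHVA_dV <- p$g_HVA * mHVA
  J["Ca", "V"] <- -p$eps * p$alpha * (dIT_dV + dIHVA_dV)
  J["Ca", "hT"] <- -p$eps * p$alpha * p$g_T * mT_inf * (V - p$E_Ca)
  J["Ca", "mHVA"] <- -p$eps * p$alpha * p$g_HVA * (V - p$E_Ca)
  J["Ca", "Ca"] <- -p$eps * p$k
  J
}

#' Analytic Jacobian of the fast subsystem
#'
#' @inheritParams fast_rhs
#' @return a 6 x 6 matrix over the fast variables.
#' @export
fast_jacobian <- function(fast_state, hA, Ca, params) {
  full <- c(fast_state[1:4], hA = hA, fast_state[5:6], Ca = Ca)
  names(full) <- state_names()
  J <- csc_jacobian(full, params)
  J[fast_state_names(), fast_state_names()]
}
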