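#' Model parameters for the stellate cell model
#'
#' Builds the full parameter set of the expanded Hodgkin-Huxley model of a
#' cerebellar stellate cell: seven ionic currents (Na, delayed-rectifier K,
#' leak, A-type K, T-type Ca, high-voltage-activated Ca, Ca-activated K), the
#' gating kinetics of each, and the cytosolic calcium balance. Two builtin
#' variants reflect the runup phenomenon seen in whole-cell recordings
#' (a temporal increase in excitability after break-in): `runup = "pre"` uses
#' the gating parameters measured right after patch formation, `runup = "post"`
#' the values measured ~25 min later. All other parameters are shared.
#'
#' Units: conductances uS/cm^2, potentials mV, time constants ms, capacitance
#' uF/cm^2, currents uA/cm^2, calcium uM.
#'
#' @param runup `"post"` (default) or `"pre"`, selecting the runup variant.
#' @param ... named overrides of individual parameters, e.g. `g_HVA = 0.235`.
#' @return An object of class `csc_params`: a named list of numeric scalars.
#' @examples
#' p <- csc_params("post", g_HVA = 0.235)
#' p$g_HVA
#' @export
csc_params <- function(runup = c("post", "pre"), ...) {
  runup <- match.arg(runup)
  p <- list(
    C = 1.50148, I_app = 0,
    g_Na = 3.4, g_K = 20.25, g_L = 0.07407, g_A = 12.2, g_T = 0.45045,
    g_HVA = 0.08, g_KCa = 1.0,
    E_Na = 55, E_K = -80, E_L = -38, E_Ca = 22,
    # gating: half-activation v, slope s, constant time constants tau
    v_m = -37, s_m = 3,                      # Na activation (instantaneous)
    v_h = -40, s_h = -4,                     # Na inactivation, tau_h(V)
    v_n = -26, s_n = 6,                      # K activation, tau_n(V)
    v_nA = -27, s_nA = 13.2, tau_nA = 5,     # A-type activation
    v_hA = -82, s_hA = -6.5, tau_hA = 10,    # A-type inactivation
    v_mT = -54, s_mT = 3,                    # T-type activation (instantaneous)
    v_hT = -74, s_hT = -3.75, tau_hT = 15,   # T-type inactivation
    v_mHVA = -25, s_mHVA = 8, tau_mHVA = 4,  # HVA activation
    # tau_h(V) Lorentzian: y0 + (2*A/pi) * w / (4 (V - Vc)^2 + w^2)
    y0 = 0.1, A = 322, w = 46, Vc = -74,
    # calcium handling
    k_Ca = 0.45, alpha = 0.018, k = 0.1, eps = 0.015,
    runup = runup
  )
  if (runup == "post") {
    p$v_m <- -45.2; p$s_m <- 2.3
    p$v_h <- -51.5
    p$v_nA <- -41
    p$v_hA <- -95; p$s_hA <- -9.2
  }
  p <- csc_set(structure(p, class = "csc_params"), ...)
  p
}

#' Override parameters in a parameter set
#'
#' @param params a `csc_params` object.
#' @param ... named numeric overrides; unknown names are an error.
#' @return the modified `csc_params` object.
#' @export
csc_set <- function(params, ...) {
  ov <- list(...)
  if (length(ov) == 0) return(params)
  bad <- setdiff(names(ov), names(params))
  if (length(bad) > 0 || is.null(names(ov)) || any(names(ov) == "")) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  }
  for (nm in names(ov)) {
    if (nm == "runup") {
      params[[nm]] <- match.arg(ov[[nm]], c("post", "pre"))
    } else {
      stopifnot(is.numeric(ov[[nm]]), length(ov[[nm]]) == 1)
      params[[nm]] <- as.numeric(ov[[nm]])
    }
  }
  validate_params(params)
  params
}

validate_params <- function(p) {
  conds <- c("g_Na", "g_K", "g_L", "g_A", "g_T", "g_HVA", "g_KCa")
  if (any(unlist(p[conds]) < 0)) stop("conductances must be >= 0")
  if (p$C <= 0) stop("C must be > 0")
  if (p$k_Ca <= 0) stop("k_Ca must be > 0")
  if (p$eps <= 0) stop("eps must be > 0")
  if (p$w <= 0) stop("w must be > 0")
  invisible(p)
}

#' @export
print.csc_params <- function(x, ...) {
  cat("<csc_params> expanded stellate-cell model,", x$runup, "runup\n")
  num <- x[setdiff(names(x), "runup")]
  df <- data.frame(parameter = names(num), value = unlist(num),
                   row.names = NULL)
  print(df, ...)
  invisible(x)
}

#' Tidy a parameter set into a tibble
#'
#' @param x a `csc_params` object.
#' @param ... unused.
#' @return a tibble with columns `parameter`, `value`, `unit`.
#' @export
tidy.csc_params <- function(x, ...) {
  units <- c(
    C = "uF/cm^2", I_app = "uA/cm^2",
    g_Na = "uS/cm^2", g_K = "uS/cm^2", g_L = "uS/cm^2", g_A = "uS/cm^2",
    g_T = "uS/cm^2", g_HVA = "uS/cm^2", g_KCa = "uS/cm^2",
    E_Na = "mV", E_K = "mV", E_L = "mV", E_Ca = "mV",
    v_m = "mV", s_m = "mV", v_h = "mV", s_h = "mV", v_n = "mV", s_n = "mV",
    v_nA = "mV", s_nA = "mV", tau_nA = "ms",
    v_hA = "mV", s_hA = "mV", tau_hA = "ms",
    v_mT = "mV", s_mT = "mV", v_hT = "mV", s_hT = "mV", tau_hT = "ms",
    v_mHVA = "mV", s_mHVA = "mV", tau_mHVA = "ms",
    y0 = "ms", A = "ms.mV", w = "mV", Vc = "mV",
    k_Ca = "uM", alpha = "uM.cm^2/(uA.ms)", k = "1/ms", eps = ""
  )
  nm <- setdiff(names(x), "runup")
  tibble::tibble(parameter = nm,
                 value = vapply(x[nm], as.numeric, 1),
                 unit = unname(units[nm]))
}

# order must match src/cscmodel.c
.csc_param_vector <- function(p, protocol = NULL, hA = 0, Ca = 0) {
  pr <- protocol_vector(protocol)
  c(p$C, p$I_app, p$g_Na, p$g_K, p$g_L, p$g_A, p$g_T, p$g_HVA, p$g_KCa,
    p$E_Na, p$E_K, p$E_L, p$E_Ca,
    p$v_m, p$s_m, p$v_h, p$s_h, p$v_n, p$s_n,
    p$v_nA, p$s_nA, p$tau_nA, p$v_hA, p$s_hA, p$tau_hA,
    p$v_mT, p$s_mT, p$v_hT, p$s_hT, p$tau_hT,
    p$v_mHVA, p$s_mHVA, p$tau_mHVA,
    p$y0, p$A, p$w, p$Vc,
    p$k_Ca, p$alpha, p$k, p$eps,
    pr, hA, Ca)
}

state_names <- function() c("V", "h", "n", "nA", "hA", "hT", "mHVA", "Ca")
fast_state_names <- function() c("V", "h", "n", "nA", "hT", "mHVA")
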