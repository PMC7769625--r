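#' Equilibria of the full system by closed-form reduction
#'
#' At a fixed point every stored gate sits at its voltage steady state and
#' calcium at its balance value `Ca* = -alpha (I_T + I_HVA) / k`, so the
#' eight equilibrium conditions reduce to a single current-balance equation
#' in `V`. That scalar equation is bracketed on a dense grid over `V_range`
#' and each root is polished with [stats::uniroot()]; full states and
#' eigenvalue spectra are assembled from the roots. This reduction serves as
#' the independent oracle against which continuation output is checked.
#'
#' @param params a [csc_params()] set.
#' @param V_range search interval (mV).
#' @param n_grid number of bracketing grid points.
#' @return a `csc_equilibria` tibble: one row per equilibrium with the state
#'   columns, `max_re` (leading eigenvalue real part), `stable`, and the
#'   eigenvalues as a list column `eigenvalues`.
#' @export
find_equilibria <- function(params, V_range = c(-120, 20), n_grid = 1401) {
  f <- function(V) csc_rhs(equilibrate_at_hold(params, V), params)[["V"]]
  roots <- bracket_roots(f, V_range, n_grid)
  out <- purrr::map_dfr(roots, function(V) {
    st <- equilibrate_at_hold(params, V)
    ev <- eigen(csc_jacobian(st, params), only.values = TRUE)$values
    c(as.list(st), list(max_re = max(Re(ev)), stable = max(Re(ev)) < 0,
                        eigenvalues = list(ev)))
  })
  class(out) <- c("csc_equilibria", class(out))
  out
}

#' Equilibria of the fast subsystem at frozen slow variables
#'
#' Same scalar-reduction oracle as [find_equilibria()], with `hA` and `Ca`
#' frozen: gates at steady state, one current-balance equation in `V`,
#' stability from the 6x6 Jacobian. Sheets of the critical manifold are
#' slices of this computation.
#'
#' @inheritParams find_equilibria
#' @param hA,Ca frozen slow-variable values.
#' @return a `csc_equilibria` tibble over the fast state columns.
#' @export
fast_equilibria <- function(params, hA, Ca, V_range = c(-120, 20),
                            n_grid = 1401) {
  f <- function(V) {
    st <- fast_steady_gates(params, V)
    fast_rhs(st, hA, Ca, params)[["V"]]
  }
  roots <- bracket_roots(f, V_range, n_grid)
  out <- purrr::map_dfr(roots, function(V) {
    st <- fast_steady_gates(params, V)
    ev <- eigen(fast_jacobian(st, hA, Ca, params), only.values = TRUE)$values
    c(as.list(st), list(max_re = max(Re(ev)), stable = max(Re(ev)) < 0,
                        eigenvalues = list(ev)))
  })
  class(out) <- c("csc_equilibria", class(out))
  out
}

fast_steady_gates <- function(params, V) {
  p <- params
  c(V = V,
    h = gate_steady_state(V, p$v_h, p$s_h),
    n = gate_steady_state(V, p$v_n, p$s_n),
    nA = gate_steady_state(V, p$v_nA, p$s_nA),
    hT = gate_steady_state(V, p$v_hT, p$s_hT),
    mHVA = gate_steady_state(V, p$v_mHVA, p$s_mHVA))
}

bracket_roots <- function(f, range, n_grid, tol = 1e-12) {
  Vs <- seq(range[1], range[2], length.out = n_grid)
  fv <- vapply(Vs, f, 1)
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1)) {
    if (!is.finite(fv[i]) || !is.finite(fv[i + 1])) next
    if (fv[i] == 0) roots <- c(roots, Vs[i])
    else if (fv[i] * fv[i + 1] < 0) {
      roots <- c(roots, uniroot(f, c(Vs[i], Vs[i + 1]), tol = tol)$root)
    }
  }
  roots
}

# residual and Jacobian access shared by the continuation code:
# `fast = FALSE` -> 8-state full system, parameters as named;
# `fast = TRUE`  -> 6-state subsystem with frozen hA/Ca, which may themselves
#                   be the continuation parameter ("hA" or "Ca").
cont_system <- function(params, par_name, fast = FALSE, hA = NULL, Ca = NULL) {
  if (!fast) {
    stopifnot(par_name %in% names(params))
    list(
      n = 8L,
      state_names = state_names(),
      F = function(x, p) {
        pp <- params; pp[[par_name]] <- p
        unname(csc_rhs(setNames(x, state_names()), pp))
      },
      J = function(x, p) {
        pp <- params; pp[[par_name]] <- p
        unname(csc_jacobian(setNames(x, state_names()), pp))
      },
      start = function(p) {
        pp <- params; pp[[par_name]] <- p
        find_equilibria(pp)
      }
    )
  } else {
    stopifnot(par_name %in% c("hA", "Ca") || par_name %in% names(params))
    frozen <- c(hA = hA, Ca = Ca)
    get_frozen <- function(p) {
      fr <- frozen
      if (par_name %in% c("hA", "Ca")) fr[[par_name]] <- p
      fr
    }
    get_params <- function(p) {
      pp <- params
      if (!par_name %in% c("hA", "Ca")) pp[[par_name]] <- p
      pp
    }
    list(
      n = 6L,
      state_names = fast_state_names(),
      F = function(x, p) {
        fr <- get_frozen(p)
        unname(fast_rhs(setNames(x, fast_state_names()),
                        fr[["hA"]], fr[["Ca"]], get_params(p)))
      },
      J = function(x, p) {
        fr <- get_frozen(p)
        unname(fast_jacobian(setNames(x, fast_state_names()),
                             fr[["hA"]], fr[["Ca"]], get_params(p)))
      },
      start = function(p) {
        fr <- get_frozen(p)
        fast_equilibria(get_params(p), fr[["hA"]], fr[["Ca"]])
      }
    )
  }
}
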