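#' Integrate the fast subsystem from an arbitrary state for a fixed time
#'
#' Internal flow map used by the shooting code: no output grid, just the
#' end state, at tight tolerance.
#' @noRd
fast_flow <- function(x0, Tend, params, hA, Ca, rtol = 1e-10, atol = 1e-10,
                      dense = FALSE) {
  pv <- .csc_param_vector(params, NULL, hA = hA, Ca = Ca)
  times <- if (dense) seq(0, Tend, length.out = 201) else c(0, Tend)
  out <- deSolve::ode(y = setNames(as.numeric(x0), fast_state_names()),
                      times = times, func = "csc_fast_derivs", parms = pv,
                      dllname = "cscburst", initfunc = "csc_initmod",
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 100000)
  if (dense) out else out[nrow(out), -1]
}

# monodromy matrix by central differences around the orbit
monodromy <- function(x0, Tend, params, hA, Ca, eps = 1e-6) {
  base <- fast_flow(x0, Tend, params, hA, Ca)
  M <- matrix(0, 6, 6)
  for (j in 1:6) {
    e <- rep(0, 6)
    e[j] <- eps * max(1, abs(x0[j]))
    M[, j] <- (fast_flow(x0 + e, Tend, params, hA, Ca) -
                 fast_flow(x0 - e, Tend, params, hA, Ca)) / (2 * e[j])
  }
  list(M = M, phi = base)
}

#' Converge a periodic orbit of the fast subsystem by single shooting
#'
#' Newton iteration on the unknowns (initial state, period) with the
#' periodicity condition and an orthogonality phase condition (the
#' correction is kept orthogonal to the flow at the current point).
#'
#' @param params a [csc_params()] set.
#' @param hA,Ca frozen slow values.
#' @param x0 initial state guess (6 components).
#' @param T0 period guess (ms).
#' @param tol Newton residual tolerance.
#' @param max_iter Newton iterations.
#' @return a `csc_po` list: `x0`, `T`, `multipliers` (Floquet multipliers of
#'   the monodromy matrix), `stable` (all non-trivial multipliers inside the
#'   unit circle), `trivial_error` (|closest multiplier - 1|), `hA`, `Ca`,
#'   `converged`.
#' @export
po_shoot <- function(params, hA, Ca, x0, T0, tol = 1e-9, max_iter = 15) {
  x <- as.numeric(x0); Tc <- T0
  conv <- FALSE
  res_norm <- function(x, Tc) {
    max(abs(fast_flow(x, Tc, params, hA, Ca) - x))
  }
  r_prev <- res_norm(x, Tc)
  for (it in seq_len(max_iter)) {
    mon <- monodromy(x, Tc, params, hA, Ca)
    R <- mon$phi - x
    f0 <- unname(fast_rhs(setNames(x, fast_state_names()), hA, Ca, params))
    if (max(abs(R)) < tol) { conv <- TRUE; break }
    fT <- unname(fast_rhs(setNames(mon$phi, fast_state_names()), hA, Ca,
                          params))
    A <- rbind(cbind(mon$M - diag(6), fT), c(f0, 0))
    rhs <- c(R, 0)
    step <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    # damped update: keep the period positive and do not let the residual
    # blow up (plain Newton is fragile for strongly unstable orbits)
    lambda <- 1
    improved <- FALSE
    for (bt in 1:5) {
      x_try <- x - lambda * step[1:6]
      T_try <- Tc - lambda * step[7]
      if (T_try > 0.1 * T0 && T_try < 20 * T0 && all(is.finite(x_try))) {
        r_try <- tryCatch(res_norm(x_try, T_try), error = function(e) Inf)
        if (r_try < max(r_prev * 1.5, tol)) {
          x <- x_try; Tc <- T_try; r_prev <- r_try; improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  mon <- monodromy(x, Tc, params, hA, Ca)
  mult <- eigen(mon$M, only.values = TRUE)$values
  triv <- which.min(abs(mult - 1))
  structure(list(x0 = setNames(x, fast_state_names()), T = Tc,
                 multipliers = mult,
                 trivial_error = abs(mult[triv] - 1),
                 stable = all(Mod(mult[-triv]) < 1 + 1e-6),
                 hA = hA, Ca = Ca, converged = conv),
            class = "csc_po")
}

#' Seed a small periodic orbit near a Hopf bifurcation
#'
#' Builds the linear-prediction orbit at a Hopf point of the fast subsystem
#' (equilibrium plus a small displacement along the critical eigenplane,
#' period `2*pi/omega`) and polishes it with [po_shoot()] a short distance
#' past the bifurcation.
#'
#' @param params a [csc_params()] set.
#' @param hA_hopf Hopf location in `hA` (from [continue_equilibria()] or
#'   [locate_hopf_in_parameter()]).
#' @param Ca frozen calcium.
#' @param dh offset into the oscillatory side (added to `hA_hopf`).
#' @param amp initial displacement amplitude (mV scale on V).
#' @param branch_V select the equilibrium branch near this voltage.
#' @return a `csc_po` (see [po_shoot()]), with element `hA` at the offset
#'   location.
#' @export
po_from_hopf <- function(params, hA_hopf, Ca, dh = 5e-4, amp = 0.5,
                         branch_V = NULL) {
  attempt <- function(hA) {
    eq <- fast_equilibria(params, hA, Ca)
    if (nrow(eq) == 0) return(NULL)
    i <- if (is.null(branch_V)) which.max(eq$V) else
      which.min(abs(eq$V - branch_V))
    x_eq <- unlist(eq[i, fast_state_names()])
    J <- fast_jacobian(x_eq, hA, Ca, params)
    ev <- eigen(J)
    cplx <- which(Im(ev$values) > 1e-7)
    if (length(cplx) == 0) return(NULL)
    j <- cplx[which.max(Re(ev$values)[cplx])]
    omega <- Im(ev$values[j])
    vec <- Re(ev$vectors[, j])
    vec <- vec / max(abs(vec[1]), 1e-12)   # V component ~ 1
    for (a in amp * c(1, 0.5, 2)) {
      po <- po_shoot(params, hA, Ca, x_eq + a * vec, 2 * pi / omega)
      # reject convergence onto the equilibrium itself
      if (po$converged &&
          max(abs(po$x0 - x_eq)) > 10 * sqrt(.Machine$double.eps)) {
        return(po)
      }
    }
    NULL
  }
  # subcritical Hopfs carry their orbits on the stable side: try both
  for (offset in c(dh, -dh)) {
    po <- attempt(hA_hopf + offset)
    if (!is.null(po)) return(po)
  }
  stop("failed to converge a periodic orbit near the Hopf point")
}

#' Continue a family of fast-subsystem periodic orbits in hA
#'
#' Pseudo-arclength continuation of the shooting boundary-value problem
#' (initial state, period, parameter), with Floquet-multiplier event
#' detection: SNP when a non-trivial real multiplier crosses +1 at a fold of
#' the branch in the parameter, PD when a real multiplier crosses -1, and a
#' homoclinic approach (HC) when the period exceeds `hc_period_factor` times
#' the seed period while growing monotonically and the orbit passes within
#' `hc_dist` mV of a saddle equilibrium.
#'
#' @param params a [csc_params()] set.
#' @param seed a converged `csc_po` from [po_shoot()] or [po_from_hopf()].
#' @param Ca frozen calcium (taken from the seed by default).
#' @param direction `+1` or `-1`: initial direction of travel in `hA`.
#' @param hA_range admissible interval for `hA`.
#' @param h0,h_min,h_max arclength step control (normalized units).
#' @param max_points maximum branch points.
#' @param hc_period_factor,hc_dist homoclinic-approach thresholds.
#' @return a `csc_po_branch` tibble (`hA`, `T`, `l2`, `V_min`, `V_max`,
#'   `stable`, `trivial_error`, `multipliers` list column) with an `events`
#'   attribute (`type` in `"SNP"`/`"PD"`/`"HC_approach"`).
#' @export
continue_periodic_orbit <- function(params, seed, Ca = seed$Ca,
                                    direction = 1,
                                    hA_range = c(0, 1), h0 = 2e-3,
                                    h_min = 1e-7, h_max = 2e-2,
                                    max_points = 400,
                                    hc_period_factor = 10, hc_dist = 2) {
  stopifnot(inherits(seed, "csc_po"), seed$converged)
  scale <- diff(hA_range)
  n <- 6L
  # unknown vector: (x0 scaled-by-1, T scaled by T_seed, hA normalized)
  T_ref <- seed$T
  pack <- function(x0, Tc, hA) c(x0, Tc / T_ref, hA / scale)
  unpack <- function(u) list(x0 = u[1:n], T = u[n + 1] * T_ref,
                             hA = u[n + 2] * scale)

  shoot_res <- function(u) {
    s <- unpack(u)
    fast_flow(s$x0, s$T, params, s$hA, Ca) - s$x0
  }
  shoot_jac <- function(u) {
    s <- unpack(u)
    mon <- monodromy(s$x0, s$T, params, s$hA, Ca)
    fT <- unname(fast_rhs(setNames(mon$phi, fast_state_names()), s$hA, Ca,
                          params)) * T_ref
    dh <- 1e-6
    Fp <- (fast_flow(s$x0, s$T, params, s$hA + dh * scale, Ca) -
             mon$phi) / dh
    list(A = cbind(mon$M - diag(n), fT, Fp), M = mon$M)
  }

  u <- pack(seed$x0, seed$T, seed$hA)
  sj <- shoot_jac(u)
  f0 <- unname(fast_rhs(seed$x0, seed$hA, Ca, params))
  phase_row <- c(f0, 0, 0)
  tau <- qr.Q(qr(t(rbind(sj$A, phase_row))), complete = TRUE)[, n + 2]
  if (sign(tau[n + 2]) != sign(direction)) tau <- -tau

  record <- function(u, M) {
    s <- unpack(u)
    orb <- fast_flow(s$x0, s$T, params, s$hA, Ca, dense = TRUE)
    mult <- eigen(M, only.values = TRUE)$values
    triv <- which.min(abs(mult - 1))
    l2 <- sqrt(mean(rowSums(orb[, -1]^2)))
    c(list(hA = s$hA, T = s$T, l2 = l2,
           V_min = min(orb[, "V"]), V_max = max(orb[, "V"]),
           trivial_error = abs(mult[triv] - 1),
           stable = all(Mod(mult[-triv]) < 1 + 1e-6),
           multipliers = list(mult)),
      list(x0 = list(s$x0)))
  }
  pts <- list(record(u, sj$M))
  events <- list()
  h <- h0
  prev_T <- unpack(u)$T
  T_growing <- 0

  saddle_distance <- function(s) {
    eq <- fast_equilibria(params, s$hA, Ca)
    sad <- eq[!eq$stable, ]
    if (nrow(sad) == 0) return(Inf)
    orb <- fast_flow(s$x0, s$T, params, s$hA, Ca, dense = TRUE)
    min(vapply(sad$V, function(vs) min(abs(orb[, "V"] - vs)), 1))
  }

  k <- 1
  quality_tol <- 5e-3
  stalled <- FALSE
  no_progress <- 0
  while (k < max_points) {
    pred <- u + h * tau
    # phase anchor: corrections orthogonal to the flow at the last point
    s_prev <- unpack(u)
    f_prev <- unname(fast_rhs(setNames(s_prev$x0, fast_state_names()),
                              s_prev$hA, Ca, params))
    phase <- c(f_prev, 0, 0)
    sol <- NULL
    uc <- pred
    for (it in 1:10) {
      r <- c(shoot_res(uc), sum(phase * (uc - u)), sum(tau * (uc - pred)))
      if (max(abs(r)) < 1e-8) { sol <- list(u = uc, iters = it); break }
      sjc <- shoot_jac(uc)
      A <- rbind(sjc$A, phase, tau)
      step <- tryCatch(solve(A, r), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      uc <- uc - step
      if (unpack(uc)$T <= 0) break
    }
    ok <- !is.null(sol)
    if (ok) {
      sj_try <- shoot_jac(sol$u)
      cand <- record(sol$u, sj_try$M)
      # reject points whose monodromy has lost the trivial multiplier:
      # the shooting problem is no longer trustworthy there
      ok <- cand$trivial_error < quality_tol
    }
    if (!ok) {
      h <- h / 2
      if (h < h_min) { stalled <- TRUE; break }
      next
    }
    moved <- sqrt(sum((sol$u - u)^2))
    no_progress <- if (moved < 1e-5) no_progress + 1 else 0
    if (no_progress >= 5) { stalled <- TRUE; break }
    u <- sol$u
    sj <- sj_try
    tau_new <- qr.Q(qr(t(rbind(sj$A, c(unname(
      fast_rhs(setNames(unpack(u)$x0, fast_state_names()),
               unpack(u)$hA, Ca, params)), 0, 0)))),
      complete = TRUE)[, n + 2]
    if (sum(tau_new * tau) < 0) tau_new <- -tau_new
    tau <- tau_new
    if (sol$iters <= 3) h <- min(h * 1.3, h_max)
    k <- k + 1
    pts[[k]] <- record(u, sj$M)
    s <- unpack(u)

    # event tests against the previous point
    prev <- pts[[k - 1]]
    ev_now <- po_event_tests(prev, pts[[k]])
    for (e in ev_now) events[[length(events) + 1]] <- e

    if (pts[[k]]$V_max - pts[[k]]$V_min < 0.05) {
      events[[length(events) + 1]] <- tibble::tibble(
        type = "HB_end", hA = s$hA, T = s$T,
        detail = pts[[k]]$V_max - pts[[k]]$V_min)
      break
    }
    T_growing <- if (s$T > prev_T) T_growing + 1 else 0
    prev_T <- s$T
    if (s$T > hc_period_factor * T_ref && T_growing >= 2) {
      d <- saddle_distance(s)
      if (d < hc_dist) {
        events[[length(events) + 1]] <- tibble::tibble(
          type = "HC_approach", hA = s$hA, T = s$T, detail = d)
        break
      }
    }
    if (s$hA > max(hA_range) || s$hA < min(hA_range)) break
  }
  # a stalled branch whose period was growing while the orbit hugged a
  # saddle equilibrium is a homoclinic approach: the period blows up only
  # logarithmically while the shooting conditioning collapses, so the
  # period-ratio threshold alone is rarely reached first
  if (stalled && length(pts) >= 3) {
    s <- unpack(u)
    Ts <- vapply(pts, function(q) q$T, 1)
    grew <- tail(Ts, 1) > 1.05 * Ts[1] && tail(Ts, 1) >= max(Ts) - 1e-6
    d <- saddle_distance(s)
    if (grew && d < hc_dist) {
      events[[length(events) + 1]] <- tibble::tibble(
        type = "HC_approach", hA = s$hA, T = s$T, detail = d)
    }
  }

  branch <- dplyr::bind_rows(pts)
  ev <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(type = character(), hA = numeric(), T = numeric(),
                   detail = numeric())
  structure(branch, events = ev, Ca = Ca, params = params,
            seed_period = T_ref,
            class = c("csc_po_branch", class(branch)))
}

# multiplier-based events between consecutive branch points:
# PD: most negative real multiplier crosses -1;
# SNP: fold in hA together with a non-trivial multiplier near +1
po_event_tests <- function(prev, cur) {
  out <- list()
  pd_test <- function(mult) {
    re <- Re(mult[abs(Im(mult)) < 1e-8])
    if (length(re) == 0) return(NA_real_)
    min(re) + 1
  }
  p1 <- pd_test(prev$multipliers[[1]])
  p2 <- pd_test(cur$multipliers[[1]])
  if (is.finite(p1) && is.finite(p2) && p1 * p2 < 0) {
    out[[length(out) + 1]] <- tibble::tibble(
      type = "PD", hA = cur$hA, T = cur$T, detail = min(Re(
        cur$multipliers[[1]][abs(Im(cur$multipliers[[1]])) < 1e-8])))
  }
  out
}

# detect SNP events as parameter folds of a completed branch
po_fold_events <- function(branch) {
  dh <- diff(branch$hA)
  folds <- which(dh[-length(dh)] * dh[-1] < 0) + 1
  purrr::map_dfr(folds, function(i) {
    mult <- branch$multipliers[[i]]
    nontriv <- mult[-which.min(abs(mult - 1))]
    tibble::tibble(type = "SNP", hA = branch$hA[i], T = branch$T[i],
                   detail = min(abs(nontriv - 1)))
  })
}

#' @export
print.csc_po_branch <- function(x, ...) {
  ev <- attr(x, "events")
  cat(sprintf("<csc_po_branch> %d periodic orbits, hA in [%.4g, %.4g], Ca = %g\n",
              nrow(x), min(x$hA), max(x$hA), attr(x, "Ca")))
  cat(sprintf("period %.3g .. %.3g ms; %d stable points\n",
              min(x$T), max(x$T), sum(x$stable)))
  if (nrow(ev)) { cat("events:\n"); print(as.data.frame(ev)) }
  invisible(x)
}

#' @export
tidy.csc_po_branch <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x)[, c("hA", "T", "l2", "V_min", "V_max",
                                         "stable", "trivial_error")])
}

#' @export
glance.csc_po_branch <- function(x, ...) {
  ev <- attr(x, "events")
  tibble::tibble(
    n_points = nrow(x), Ca = attr(x, "Ca"),
    n_pd = sum(ev$type == "PD"),
    n_snp = sum(ev$type == "SNP"),
    n_hc = sum(ev$type == "HC_approach"),
    max_trivial_error = max(x$trivial_error),
    period_range = max(x$T) / min(x$T)
  )
}

#' Census of fast-subsystem homoclinic approaches at fixed calcium
#'
#' Reproduces the slow-fast dissection's periodic-orbit skeleton at one
#' calcium value: continues the fast-subsystem equilibria in hA, seeds a
#' periodic-orbit family at every certified Hopf point, probes a grid of hA
#' values inside the fold interval for stable spiking orbits by direct
#' simulation (the route to an isolated family, when one exists), continues
#' every family to its ends, and counts distinct homoclinic-approach events.
#'
#' @param params a [csc_params()] set.
#' @param Ca frozen calcium (uM).
#' @param hA_range search interval in hA.
#' @param probe_n number of direct-simulation probes for isolated families.
#' @param max_points per-direction continuation budget.
#' @param dedupe_tol hA separation under which two events are the same
#'   homoclinic.
#' @return a list: `n_homoclinic`, `events` (tibble), `branch` (the
#'   equilibrium branch), `families` (list of `csc_po_branch`).
#' @export
count_fast_homoclinics <- function(params, Ca = 0.25, hA_range = c(0, 0.3),
                                   probe_n = 7, max_points = 150,
                                   dedupe_tol = 2e-3) {
  br <- continue_equilibria(params, "hA", hA_range, fast = TRUE, Ca = Ca,
                            start_V = -25, h0 = 5e-3)
  ev <- branch_events(br)
  hbs <- ev$par[ev$type == "HB" & ev$certified]
  sns <- sort(ev$par[ev$type == "SN"])
  families <- list()

  for (hb in hbs) {
    seed <- tryCatch(po_from_hopf(params, hb, Ca, branch_V = -40),
                     error = function(e) NULL)
    if (is.null(seed)) next
    for (dir in c(-1, 1)) {
      fam <- tryCatch(
        continue_periodic_orbit(params, seed, Ca = Ca, direction = dir,
                                hA_range = hA_range,
                                max_points = max_points),
        error = function(e) NULL)
      if (!is.null(fam)) families[[length(families) + 1]] <- fam
    }
  }

  # probe for stable (isolated) spiking families inside the fold interval
  if (length(sns) >= 2 && probe_n > 0) {
    probes <- seq(min(sns), max(sns), length.out = probe_n + 2)
    probes <- probes[-c(1, length(probes))]
    for (hA in probes) {
      tr <- tryCatch(
        fast_simulate(params, hA, Ca, 600,
                      init = c(V = 0, h = 0.7, n = 0.2, nA = 0.4,
                               hT = 0.01, mHVA = 0.15), dt = 0.05),
        error = function(e) NULL)
      if (is.null(tr)) next
      tail_tr <- tr[tr$t > 300, ]
      sp <- detect_spikes(tail_tr, threshold = -30)
      if (length(sp) < 4) next
      Tguess <- median(diff(sp))
      i0 <- which.min(abs(tail_tr$t - sp[length(sp) - 1]))
      seed <- po_shoot(params, hA, Ca,
                       unlist(tail_tr[i0, fast_state_names()]), Tguess)
      if (!seed$converged) next
      for (dir in c(-1, 1)) {
        fam <- tryCatch(
          continue_periodic_orbit(params, seed, Ca = Ca, direction = dir,
                                  hA_range = hA_range,
                                  max_points = max_points),
          error = function(e) NULL)
        if (!is.null(fam)) families[[length(families) + 1]] <- fam
      }
    }
  }

  hc <- purrr::map_dfr(families, function(f) {
    e <- attr(f, "events")
    e[e$type == "HC_approach", ]
  })
  if (nrow(hc)) {
    hc <- hc[order(hc$hA), ]
    keep <- c(TRUE, diff(hc$hA) > dedupe_tol)
    hc <- hc[keep, ]
  }
  list(n_homoclinic = nrow(hc), events = hc, branch = br,
       families = families)
}
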