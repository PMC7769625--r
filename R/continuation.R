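#' Pseudo-arclength continuation of equilibria
#'
#' Traces a branch of equilibria of the full system (or of the fast
#' subsystem with `fast = TRUE`) as one parameter varies, using a
#' predictor-corrector scheme with pseudo-arclength parameterization so the
#' branch is followed around folds. Saddle-node events are detected by a
#' sign change of the Jacobian determinant (and certified by a single real
#' eigenvalue through zero), Hopf events by a sign change of the largest
#' real part over complex eigenvalue pairs (certified by a conjugate pair
#' with nonzero imaginary part), both refined by bisection along the branch.
#'
#' @param params a [csc_params()] set.
#' @param par_name parameter to continue in: any parameter name, or `"hA"` /
#'   `"Ca"` for the frozen slow variables when `fast = TRUE`.
#' @param range numeric length-2 parameter interval; continuation starts at
#'   `range[1]` and stops when the parameter leaves the interval.
#' @param fast continue equilibria of the 6-variable fast subsystem.
#' @param hA,Ca frozen slow values (fast subsystem only; the one named by
#'   `par_name` may be omitted).
#' @param start_V select the starting equilibrium closest to this voltage
#'   when several exist at `range[1]` (default: the most negative).
#' @param h0 initial arclength step (in normalized units where the parameter
#'   interval has length 1).
#' @param h_min,h_max step bounds; the step halves on Newton failure and
#'   grows 1.4x on quick convergence.
#' @param max_points maximum branch points.
#' @return a `csc_branch`: a tibble of branch points (parameter, state
#'   columns, `l2`, `max_re`, `stable`) with an `events` attribute (tibble
#'   with `type` in `"SN"`/`"HB"`, refined parameter location, certifying
#'   eigenvalue data). See [tidy.csc_branch()] and [glance.csc_branch()].
#' @export
continue_equilibria <- function(params, par_name, range, fast = FALSE,
                                hA = NULL, Ca = NULL, start_V = NULL,
                                h0 = 1e-3, h_min = 1e-6, h_max = 5e-2,
                                max_points = 2000) {
  sys <- cont_system(params, par_name, fast, hA, Ca)
  scale <- abs(diff(range))
  stopifnot(scale > 0)

  eq0 <- sys$start(range[1])
  if (nrow(eq0) == 0) stop("no equilibrium at the start of the range")
  i0 <- if (is.null(start_V)) which.min(eq0$V) else
    which.min(abs(eq0$V - start_V))
  x <- unlist(eq0[i0, sys$state_names])
  u <- c(unname(x), range[1] / scale)   # normalized parameter appended
  n <- sys$n

  Fn <- function(u) sys$F(u[1:n], u[n + 1] * scale)
  Jn <- function(u) {
    J <- sys$J(u[1:n], u[n + 1] * scale)
    dp <- 1e-7
    Fp <- (sys$F(u[1:n], (u[n + 1] + dp) * scale) -
             sys$F(u[1:n], (u[n + 1] - dp) * scale)) / (2 * dp)
    cbind(J, Fp)
  }
  tangent <- function(u, prev = NULL) {
    A <- Jn(u)
    tau <- qr.Q(qr(t(A)), complete = TRUE)[, n + 1]
    if (!is.null(prev) && sum(tau * prev) < 0) tau <- -tau
    tau
  }

  # polish the start point
  for (it in 1:20) {
    r <- Fn(u)
    if (max(abs(r)) < 1e-11) break
    u[1:n] <- u[1:n] - solve(sys$J(u[1:n], u[n + 1] * scale), r)
  }

  tau <- tangent(u)
  # head from range[1] toward range[2]
  if (sign(tau[n + 1]) != sign(range[2] - range[1])) tau <- -tau
  pts <- list()
  h <- h0
  record <- function(u) {
    st <- setNames(u[1:n], sys$state_names)
    ev <- eigen(sys$J(u[1:n], u[n + 1] * scale), only.values = TRUE)$values
    c(list(par = u[n + 1] * scale), as.list(st),
      list(l2 = sqrt(sum(st^2)), max_re = max(Re(ev)),
           det = det_sign_value(sys$J(u[1:n], u[n + 1] * scale)),
           hopf_test = hopf_test_value(ev), eigenvalues = list(ev)))
  }
  pts[[1]] <- record(u)

  corrector <- function(pred, tau) {
    uc <- pred
    for (it in 1:12) {
      r <- c(Fn(uc), sum(tau * (uc - pred)))
      if (max(abs(r)) < 1e-10) return(list(u = uc, iters = it))
      A <- rbind(Jn(uc), tau)
      duc <- tryCatch(solve(A, r), error = function(e) NULL)
      if (is.null(duc)) return(NULL)
      uc <- uc - duc
      if (any(!is.finite(uc))) return(NULL)
    }
    NULL
  }

  k <- 1
  while (k < max_points) {
    pred <- u + h * tau
    sol <- corrector(pred, tau)
    if (is.null(sol)) {
      h <- h / 2
      if (h < h_min) break   # step-size collapse: truncate with diagnostic
      next
    }
    u_new <- sol$u
    if (sol$iters <= 3) h <- min(h * 1.4, h_max)
    tau <- tangent(u_new, tau)
    u <- u_new
    k <- k + 1
    pts[[k]] <- record(u)
    p_now <- u[n + 1] * scale
    if (p_now > max(range) + 1e-9 || p_now < min(range) - 1e-9) break
  }

  branch <- dplyr::bind_rows(pts)
  branch$stable <- branch$max_re < 0
  events <- detect_branch_events(branch, sys, scale)
  structure(branch,
            events = events, par_name = par_name, fast = fast,
            params = params, frozen = c(hA = hA, Ca = Ca),
            truncated = (k >= max_points || h < h_min),
            class = c("csc_branch", class(branch)))
}

det_sign_value <- function(J) {
  as.numeric(determinant(J, logarithm = TRUE)$sign)
}

# largest real part over complex pairs; -Inf when no complex pair
hopf_test_value <- function(ev, im_tol = 1e-7) {
  cplx <- ev[abs(Im(ev)) > im_tol]
  if (length(cplx) == 0) return(-Inf)
  max(Re(cplx))
}

detect_branch_events <- function(branch, sys, scale, eig_zero = 1e-9) {
  events <- list()
  n <- sys$n
  for (i in seq_len(nrow(branch) - 1)) {
    d1 <- sign(branch$det[i]); d2 <- sign(branch$det[i + 1])
    if (is.finite(d1) && is.finite(d2) && d1 * d2 < 0) {
      ref <- refine_event(branch, i, sys, scale,
                          driver = function(sol) sol$det,
                          report = function(ev) nearest_zero_re(ev))
      events[[length(events) + 1]] <- tibble::tibble(
        type = "SN", par = ref$par, V = ref$V,
        test_value = ref$test, certified = abs(ref$test) < 1e-3)
    }
    h1 <- branch$hopf_test[i]; h2 <- branch$hopf_test[i + 1]
    if (is.finite(h1) && is.finite(h2) && h1 * h2 < 0) {
      ref <- refine_event(branch, i, sys, scale,
                          driver = function(sol) hopf_test_value(sol$ev),
                          report = function(ev) hopf_test_value(ev))
      events[[length(events) + 1]] <- tibble::tibble(
        type = "HB", par = ref$par, V = ref$V,
        test_value = ref$test, certified = abs(ref$test) < 1e-5)
    }
  }
  if (length(events) == 0) {
    tibble::tibble(type = character(), par = numeric(), V = numeric(),
                   test_value = numeric(), certified = logical())
  } else dplyr::bind_rows(events)
}

# real part of the eigenvalue closest to the imaginary axis (the quantity
# certified to vanish at a saddle-node)
nearest_zero_re <- function(ev) {
  Re(ev)[which.min(abs(Re(ev)))]
}

# bisection between two adjacent branch points, re-solving the equilibrium
# by Newton from linear interpolation at each trial point; `driver` supplies
# the sign test used for bisection, `report` the certifying value
refine_event <- function(branch, i, sys, scale, driver, report, iters = 50) {
  n <- sys$n
  u1 <- c(unlist(branch[i, sys$state_names]), branch$par[i])
  u2 <- c(unlist(branch[i + 1, sys$state_names]), branch$par[i + 1])
  solve_at <- function(s) {
    u <- (1 - s) * u1 + s * u2
    x <- u[1:n]; p <- u[n + 1]
    for (it in 1:25) {
      r <- sys$F(x, p)
      if (max(abs(r)) < 1e-12) break
      step <- tryCatch(solve(sys$J(x, p), r), error = function(e) NULL)
      if (is.null(step)) break
      x_new <- x - step
      # guard against Newton escaping the bracketing segment entirely
      if (abs(x_new[1] - u[1]) > 10 + 2 * abs(u2[1] - u1[1])) break
      x <- x_new
    }
    J <- sys$J(x, p)
    list(x = x, p = p, ev = eigen(J, only.values = TRUE)$values,
         det = det_sign_value(J))
  }
  a <- 0; b <- 1
  fa <- driver(solve_at(a))
  for (it in seq_len(iters)) {
    m <- (a + b) / 2
    fm <- driver(solve_at(m))
    if (is.finite(fa) && is.finite(fm) && fa * fm <= 0) b <- m
    else { a <- m; fa <- fm }
  }
  sol <- solve_at((a + b) / 2)
  list(par = sol$p, V = sol$x[1], test = report(sol$ev))
}

#' @export
print.csc_branch <- function(x, ...) {
  ev <- attr(x, "events")
  cat(sprintf("<csc_branch> %s in '%s', %d points, %s [%g, %g]\n",
              if (isTRUE(attr(x, "fast"))) "fast subsystem" else "full system",
              attr(x, "par_name"), nrow(x), "parameter range",
              min(x$par), max(x$par)))
  if (nrow(ev)) {
    cat("events:\n"); print(as.data.frame(ev))
  } else cat("no bifurcation events detected\n")
  invisible(x)
}

#' @export
tidy.csc_branch <- function(x, ...) {
  cols <- c("par", intersect(state_names(), names(x)), "l2", "max_re",
            "stable")
  out <- tibble::as_tibble(as.data.frame(x)[, cols])
  names(out)[1] <- "parameter"
  out
}

#' @export
glance.csc_branch <- function(x, ...) {
  ev <- attr(x, "events")
  tibble::tibble(
    par_name = attr(x, "par_name"),
    n_points = nrow(x),
    n_sn = sum(ev$type == "SN"),
    n_hopf = sum(ev$type == "HB"),
    par_min = min(x$par), par_max = max(x$par),
    truncated = isTRUE(attr(x, "truncated"))
  )
}

#' Branch events
#' @param branch a `csc_branch` or `csc_po_branch`.
#' @return the events tibble attached to the branch.
#' @export
branch_events <- function(branch) attr(branch, "events")

#' Locate a Hopf bifurcation by bisection in a parameter
#'
#' Bisects the largest real part of the complex eigenvalue pair of the
#' equilibrium (re-solved from the closed-form reduction at every trial
#' parameter) over a bracketing interval.
#'
#' @inheritParams continue_equilibria
#' @param bracket length-2 interval known to bracket the sign change.
#' @param branch_V follow the equilibrium closest to this voltage (defaults
#'   to the single equilibrium when unique).
#' @param tol parameter tolerance.
#' @return the parameter value at the Hopf point, with attributes
#'   `V` (equilibrium voltage) and `test_value` (residual real part).
#' @export
locate_hopf_in_parameter <- function(params, par_name, bracket,
                                     fast = FALSE, hA = NULL, Ca = NULL,
                                     branch_V = NULL, tol = 1e-3) {
  sys <- cont_system(params, par_name, fast, hA, Ca)
  test_at <- function(p) {
    eq <- sys$start(p)
    if (nrow(eq) == 0) return(NULL)
    i <- if (is.null(branch_V)) which.min(eq$V) else
      which.min(abs(eq$V - branch_V))
    list(test = hopf_test_value(eq$eigenvalues[[i]]), V = eq$V[i])
  }
  a <- min(bracket); b <- max(bracket)
  ta <- test_at(a); tb <- test_at(b)
  if (is.null(ta) || is.null(tb) || !is.finite(ta$test) ||
      !is.finite(tb$test) || ta$test * tb$test > 0) {
    stop("bracket does not enclose a Hopf sign change")
  }
  while (b - a > tol) {
    m <- (a + b) / 2
    tm <- test_at(m)
    if (is.null(tm) || !is.finite(tm$test)) stop("lost the branch during bisection")
    if (ta$test * tm$test <= 0) { b <- m; tb <- tm } else { a <- m; ta <- tm }
  }
  m <- (a + b) / 2
  tm <- test_at(m)
  structure(m, V = tm$V, test_value = tm$test)
}

#' Classify a fold of equilibria as SNIC or non-SNIC
#'
#' Locates the saddle-node of the resting branch in the applied current,
#' then simulates just above it and tests the square-root frequency law of a
#' saddle-node-on-invariant-circle bifurcation: firing frequency
#' `f = c * sqrt(I - I_SN)`, i.e. `f^2` linear in the distance to the fold.
#' The fit must achieve `R^2 > 0.99` over a decade of distances and the
#' limit cycle must disappear just below the fold (no sustained firing) for
#' the SNIC label.
#'
#' @param params a [csc_params()] set.
#' @param I_range interval of applied current (uA/cm^2) known to contain the
#'   fold of the resting branch.
#' @param distances distances above the fold at which frequency is measured.
#' @param duration simulation length per probe (ms).
#' @param r2_min required coefficient of determination.
#' @return a list: `label` (`"SNIC"` or `"non-SNIC"`), `I_SN`, `r2`,
#'   `fit` (tibble of distance, frequency), `below_quiet`.
#' @export
classify_snic <- function(params, I_range = c(-3, 1),
                          distances = c(0.01, 0.02, 0.04, 0.06, 0.1),
                          duration = 8000, r2_min = 0.99) {
  # fold of the lower (resting) pair: largest I with >= 3 equilibria
  has_rest_pair <- function(I) {
    nrow(find_equilibria(csc_set(params, I_app = I), c(-120, 0), 1201)) >= 3
  }
  a <- I_range[1]; b <- I_range[2]
  if (!has_rest_pair(a)) stop("no resting equilibrium pair at I_range[1]")
  while (b - a > 1e-5) {
    m <- (a + b) / 2
    if (has_rest_pair(m)) a <- m else b <- m
  }
  I_SN <- (a + b) / 2

  freq_at <- function(I) {
    p <- csc_set(params, I_app = I)
    tr <- csc_simulate(p, duration, dt = 0.1,
                       init = equilibrate_at_hold(p, -75))
    sp <- detect_spikes(tr)
    sp <- sp[sp > duration * 0.3]
    if (length(sp) < 4) return(NA_real_)
    1000 / median(diff(sp))
  }
  fit_df <- tibble::tibble(distance = distances,
                           frequency = vapply(I_SN + distances, freq_at, 1))
  ok <- is.finite(fit_df$frequency)
  below_quiet <- is.na(freq_at(I_SN - 0.05))
  if (sum(ok) < 3) {
    return(list(label = "non-SNIC", I_SN = I_SN, r2 = NA_real_,
                fit = fit_df, below_quiet = below_quiet,
                note = "insufficient firing above the fold"))
  }
  fit <- lm(I(frequency^2) ~ distance, data = fit_df[ok, ])
  r2 <- summary(fit)$r.squared
  label <- if (r2 > r2_min && below_quiet && coef(fit)[2] > 0) "SNIC"
           else "non-SNIC"
  list(label = label, I_SN = I_SN, r2 = r2, fit = fit_df,
       below_quiet = below_quiet)
}
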