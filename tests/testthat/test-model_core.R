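test_that("gating steady state is a correctly oriented sigmoid", {
  # midpoint, including the Na activation midpoint from the parameter table
  expect_equal(gate_steady_state(-37, -37, 3), 0.5)
  expect_equal(gate_steady_state(-45.2, post_params$v_m, post_params$s_m),
               0.5)
  # monotonicity and range for both slope signs
  V <- seq(-100, 20, by = 1)
  up <- gate_steady_state(V, -40, 5)
  down <- gate_steady_state(V, -40, -4)
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(down) < 0))
  expect_true(all(up > 0 & up < 1))
  expect_equal(gate_steady_state(1e4, -40, -4), 0, tolerance = 1e-12)
  expect_error(gate_steady_state(-40, -40, 0), "non-zero")
})

test_that("tau_h is a Lorentzian peaked at Vc with floor y0", {
  p <- post_params
  expect_equal(tau_h(p$Vc, p), 0.1 + 2 * 322 / (pi * 46), tolerance = 1e-12)
  expect_equal(tau_h(p$Vc, p), 4.556, tolerance = 1e-3)
  expect_equal(tau_h(1e6, p), p$y0, tolerance = 1e-6)
  expect_equal(tau_h(p$Vc + 10, p), tau_h(p$Vc - 10, p))
  expect_true(all(diff(tau_h(seq(p$Vc, 0, by = 1), p)) < 0))
})

test_that("tau_n decreases from 6 ms to 0 with midpoint 3 ms at -23 mV", {
  expect_equal(tau_n(-23), 3)
  expect_equal(tau_n(-1e4), 6, tolerance = 1e-12)
  expect_equal(tau_n(1e4), 0, tolerance = 1e-12)
  V <- seq(-100, 20, by = 0.5)
  expect_true(all(diff(tau_n(V)) < 0))
  expect_true(all(tau_n(V) > 0 & tau_n(V) < 6))
})

test_that("ionic currents vanish at their reversal potentials", {
  p <- post_params
  st <- csc_state(V = p$E_K, h = 0.5, n = 0.5, nA = 0.5, hA = 0.5,
                  hT = 0.5, mHVA = 0.5, Ca = 0.45)
  I <- ionic_currents(st, p)
  expect_equal(unname(I[c("I_K", "I_A", "I_KCa")]), c(0, 0, 0))
  st2 <- csc_state(V = p$E_Ca, h = 0, n = 0, nA = 0, hA = 0, hT = 0,
                   mHVA = 0, Ca = 0)
  I2 <- ionic_currents(st2, p)
  expect_equal(unname(I2[setdiff(names(I2), "I_L")]), rep(0, 6))
  expect_equal(I2[["I_L"]], p$g_L * (p$E_Ca - p$E_L))
})

test_that("the K(Ca) Hill factor is half-activated at Ca = k_Ca", {
  p <- post_params
  st <- csc_state(V = 0, h = 0, n = 0, nA = 0, hA = 0, hT = 0, mHVA = 0,
                  Ca = p$k_Ca)
  I <- ionic_currents(st, p)
  expect_equal(I[["I_KCa"]], p$g_KCa * 0.5 * (0 - p$E_K))
})

test_that("calcium decays by pure extrusion when Ca currents are off", {
  p <- csc_set(post_params, g_T = 0, g_HVA = 0)
  st <- csc_state(V = -50, h = 0.2, n = 0.2, nA = 0.2, hA = 0.2, hT = 0.2,
                  mHVA = 0.2, Ca = 0.3)
  d <- csc_rhs(st, p)
  expect_lt(d[["Ca"]], 0)
  expect_equal(d[["Ca"]], -p$eps * p$k * 0.3)
})

test_that("rhs rejects non-finite states", {
  st <- equilibrate_at_hold(post_params, -60)
  st["V"] <- NaN
  expect_error(csc_rhs(st, post_params), "non-finite")
})

test_that("analytic Jacobian matches central finite differences", {
  for (p in list(post_params, pre_params,
                 csc_set(post_params, g_HVA = 0.249, g_KCa = 4))) {
    for (V in c(-70, -45, -20)) {
      st <- equilibrate_at_hold(p, V)
      st["Ca"] <- st[["Ca"]] + 0.1    # off the Ca nullcline
      J <- csc_jacobian(st, p)
      Jnum <- numerical_jacobian(st, p)
      expect_equal(unname(J), Jnum, tolerance = 1e-5)
    }
  }
})

test_that("Jacobian structure reflects the equations", {
  p <- post_params
  st <- equilibrate_at_hold(p, -55)
  J <- csc_jacobian(st, p)
  expect_equal(J["nA", "nA"], -1 / p$tau_nA)
  expect_equal(J["hA", "hA"], -1 / p$tau_hA)
  expect_equal(J["hT", "hT"], -1 / p$tau_hT)
  expect_equal(J["mHVA", "mHVA"], -1 / p$tau_mHVA)
  # Ca does not feed back on the Ca currents, only on extrusion
  expect_equal(J["Ca", "Ca"], -p$eps * p$k)
  expect_equal(unname(J["Ca", c("h", "n", "nA", "hA")]), rep(0, 4))
})

test_that("fast subsystem agrees with the full system at frozen slow values", {
  p <- csc_set(post_params, g_HVA = 0.249)
  tr <- tonic_post()
  for (i in c(10000, 30000, 50000)) {
    full <- unlist(tr[i, state_names()])
    d_full <- csc_rhs(full, post_params)
    d_fast <- fast_rhs(full[fast_state_names()], full[["hA"]], full[["Ca"]],
                       post_params)
    expect_equal(d_fast, d_full[fast_state_names()], tolerance = 1e-12)
  }
  # fast Jacobian is the corresponding block of the full one
  st <- equilibrate_at_hold(p, -50)
  Jf <- fast_jacobian(st[fast_state_names()], st[["hA"]], st[["Ca"]], p)
  J <- csc_jacobian(st, p)
  expect_equal(Jf, J[fast_state_names(), fast_state_names()])
})

test_that("fast-subsystem equilibria satisfy the scalar voltage-balance oracle", {
  p <- csc_set(post_params, g_HVA = 0.249)
  eq <- fast_equilibria(p, hA = 0.02, Ca = 0.25)
  expect_gte(nrow(eq), 1)
  for (i in seq_len(nrow(eq))) {
    st <- unlist(eq[i, c("V", "h", "n", "nA", "hT", "mHVA")])
    expect_lt(max(abs(fast_rhs(st, 0.02, 0.25, p))), 1e-9)
    # gates really are at steady state
    expect_equal(st[["n"]], gate_steady_state(st[["V"]], p$v_n, p$s_n))
  }
})

test_that("compiled and R right-hand sides agree along a trajectory", {
  # the integrator uses the C implementation; csc_rhs is the R mirror
  tr <- tonic_post()
  idx <- seq(2000, nrow(tr) - 1, length.out = 25)
  for (i in round(idx)) {
    st <- unlist(tr[i, state_names()])
    d_analytic <- csc_rhs(st, post_params)
    # central difference of the dense output as an independent check
    dt <- tr$t[i + 1] - tr$t[i - 1]
    d_numeric <- (unlist(tr[i + 1, state_names()]) -
                    unlist(tr[i - 1, state_names()])) / dt
    expect_equal(unname(d_numeric), unname(d_analytic), tolerance = 5e-2)
  }
})

test_that("parameter presets differ only in the runup-sensitive entries", {
  differing <- c("v_m", "s_m", "v_h", "v_nA", "v_hA", "s_hA", "runup")
  for (nm in setdiff(names(post_params), differing)) {
    expect_identical(post_params[[nm]], pre_params[[nm]])
  }
  expect_identical(pre_params$v_m, -37)
  expect_identical(post_params$v_m, -45.2)
  expect_error(csc_set(post_params, g_Na = -1), "conductances")
  expect_error(csc_set(post_params, not_a_param = 1), "unknown parameter")
})
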