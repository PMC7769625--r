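test_that("closed-form equilibria are genuine fixed points", {
  for (p in list(post_params, csc_set(post_params, g_HVA = 0.249,
                                      g_KCa = 30))) {
    eq <- find_equilibria(p)
    expect_gte(nrow(eq), 1)
    for (i in seq_len(nrow(eq))) {
      st <- unlist(eq[i, state_names()])
      expect_lt(max(abs(csc_rhs(st, p))), 1e-10)
    }
  }
})

test_that("far above the upper Hopf in g_KCa a stable equilibrium exists", {
  eq <- find_equilibria(csc_set(post_params, g_HVA = 0.249, g_KCa = 30))
  expect_true(any(eq$stable))
})

test_that("equilibrium continuation agrees with the scalar-reduction oracle", {
  p <- csc_set(post_params, g_HVA = 0.249)
  br <- continue_equilibria(p, "g_KCa", c(10, 26), start_V = -52)
  idx <- seq(1, nrow(br), by = 10)
  for (i in idx) {
    pp <- csc_set(p, g_KCa = br$par[i])
    eq <- find_equilibria(pp)
    expect_lt(min(abs(eq$V - br$V[i])), 1e-8)
  }
})

test_that("the upper Hopf in g_KCa is certified and matches bisection", {
  p <- csc_set(post_params, g_HVA = 0.249)
  br <- continue_equilibria(p, "g_KCa", c(10, 26), start_V = -52)
  ev <- branch_events(br)
  hb <- ev[ev$type == "HB", ]
  expect_equal(nrow(hb), 1)
  expect_true(hb$certified)
  expect_lt(abs(hb$test_value), 1e-6)
  # independent detector: bisection on the eigenvalue crossing
  hb_bis <- locate_hopf_in_parameter(p, "g_KCa", c(15, 24))
  expect_lt(abs(hb_bis - hb$par) / hb$par, 0.01)
  expect_lt(abs(attr(hb_bis, "test_value")), 1e-5)
})

test_that("eigenvalue certificates hold at detected events", {
  p <- csc_set(post_params, g_HVA = 0.249)
  br <- continue_equilibria(p, "hA", c(0, 0.3), fast = TRUE, Ca = 0.25,
                            start_V = -25, h0 = 5e-3)
  ev <- branch_events(br)
  # Z-shaped slice: two saddle-nodes and one certified upper-branch Hopf
  expect_equal(sum(ev$type == "SN"), 2)
  expect_gte(sum(ev$type == "HB" & ev$certified), 1)
  hb <- ev[ev$type == "HB" & ev$certified, ][1, ]
  eq <- fast_equilibria(p, hb$par, 0.25)
  i <- which.min(abs(eq$V - hb$V))
  lam <- eq$eigenvalues[[i]]
  pair <- lam[abs(Im(lam)) > 1e-7]
  expect_gte(length(pair), 2)
  expect_lt(min(abs(Re(pair))), 1e-4)
  # SN certificate: a real eigenvalue passes through zero between the
  # bracketing branch points (certified within the refinement tolerance)
  sn <- ev[ev$type == "SN", ]
  expect_true(all(abs(sn$test_value) < 1e-2))
})

test_that("branch retraces itself when continued back", {
  p <- csc_set(post_params, g_HVA = 0.249)
  br <- continue_equilibria(p, "g_KCa", c(10, 14), start_V = -51)
  br_back <- continue_equilibria(p, "g_KCa", c(14, 10),
                                 start_V = br$V[nrow(br)])
  # same equilibrium curve: compare V at a common parameter value
  common <- 12
  V1 <- approx(br$par, br$V, xout = common)$y
  V2 <- approx(br_back$par, br_back$V, xout = common)$y
  # agreement limited by linear interpolation between branch points
  expect_equal(V1, V2, tolerance = 1e-3)
})

test_that("the resting fold in applied current is a SNIC (both presets)", {
  for (p in list(post_params, pre_params)) {
    res <- classify_snic(p, duration = 6000)
    expect_identical(res$label, "SNIC")
    expect_gt(res$r2, 0.99)
    expect_true(res$below_quiet)
    expect_lt(res$I_SN, 0)   # the cell fires spontaneously at I = 0
  }
})

test_that("frequency drops toward zero approaching the SNIC from above", {
  res <- classify_snic(post_params, duration = 6000)
  f <- res$fit$frequency
  expect_true(all(diff(f) > 0))     # monotone in the distance to the fold
  expect_lt(f[1], 0.5 * f[length(f)])
})

test_that("shooting converges periodic orbits with a clean trivial multiplier", {
  p <- csc_set(post_params, g_HVA = 0.249)
  br <- continue_equilibria(p, "hA", c(0, 0.3), fast = TRUE, Ca = 0.25,
                            start_V = -25, h0 = 5e-3)
  ev <- branch_events(br)
  hb <- ev$par[ev$type == "HB" & ev$certified][1]
  seed <- po_from_hopf(p, hb, 0.25, branch_V = -40)
  expect_true(seed$converged)
  expect_lt(seed$trivial_error, 1e-4)
  expect_gt(seed$T, 0)
  # subcritical Hopf: the emanating orbits are unstable
  expect_false(seed$stable)
})

test_that("the Hopf orbit family ends in a homoclinic approach", {
  p <- csc_set(post_params, g_HVA = 0.249)
  br <- continue_equilibria(p, "hA", c(0, 0.3), fast = TRUE, Ca = 0.25,
                            start_V = -25, h0 = 5e-3)
  ev <- branch_events(br)
  hb <- ev$par[ev$type == "HB" & ev$certified][1]
  seed <- po_from_hopf(p, hb, 0.25, branch_V = -40)
  fam <- continue_periodic_orbit(p, seed, direction = -1, max_points = 120)
  ev_po <- branch_events(fam)
  expect_equal(sum(ev_po$type == "HC_approach"), 1)
  # period grows toward the homoclinic
  expect_gt(max(fam$T), 1.1 * fam$T[1])
  # trivial Floquet multiplier within tolerance on the trustworthy part
  expect_lt(median(fam$trivial_error), 1e-3)
  expect_lt(min(fam$trivial_error), 1e-5)
})

test_that("a tiny sweep inside the tonic regime is uniformly tonic", {
  m <- regime_sweep(post_params,
                    axis1 = list(name = "g_HVA", values = c(0.08, 0.1)),
                    axis2 = list(name = "g_KCa", values = c(0.8, 1.0)),
                    duration = 5000)
  expect_true(all(m$regime == "T"))
  g <- glance(m)
  expect_identical(g$n_T, 4L)
})
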