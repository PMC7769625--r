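test_that("post-runup defaults fire tonically with constant ISI", {
  tr <- tonic_post()
  sp <- detect_spikes(tr)
  sp <- sp[sp > 500]
  expect_gt(length(sp), 20)
  isi <- diff(sp)
  expect_lt(sd(isi) / mean(isi), 0.01)
  rate <- 1000 / mean(isi)
  expect_gt(rate, 5)   # spontaneously active in the tonic range
})

test_that("pre-runup fires slower than post-runup (runup raises excitability)", {
  rate <- function(tr) {
    sp <- detect_spikes(tr); sp <- sp[sp > 500]
    1000 * length(sp) / (max(tr$t) - 500)
  }
  expect_gt(rate(tonic_post()), rate(tonic_pre()))
})

test_that("leak-only membrane relaxes exponentially to E_L with tau = C/g_L", {
  p <- csc_set(post_params, g_Na = 0, g_K = 0, g_A = 0, g_T = 0,
               g_HVA = 0, g_KCa = 0)
  init <- equilibrate_at_hold(p, -70)
  tr <- csc_simulate(p, 100, init = init, dt = 0.05)
  tau <- p$C / p$g_L
  expected <- p$E_L + (-70 - p$E_L) * exp(-tr$t / tau)
  expect_equal(tr$V, expected, tolerance = 1e-5)
})

test_that("integration is deterministic and tolerance-converged", {
  p <- post_params
  tr1 <- csc_simulate(p, 1500, dt = 0.05)
  tr2 <- csc_simulate(p, 1500, dt = 0.05)
  expect_identical(tr1$V, tr2$V)
  # halving tolerances moves spike times by well under 0.5 ms
  tr3 <- csc_simulate(p, 1500, dt = 0.05, rtol = 5e-9, atol = 5e-9)
  s1 <- detect_spikes(tr1); s3 <- detect_spikes(tr3)
  s1 <- s1[s1 > 500]; s3 <- s3[s3 > 500]
  n <- min(length(s1), length(s3))
  expect_lt(max(abs(s1[1:n] - s3[1:n])), 0.5)
})

test_that("dense output resolves spike upstrokes", {
  tr <- tonic_post()
  up <- which(diff(tr$V) > 0 & tr$V[-1] > -30 & tr$V[-1] < 0)
  expect_true(all(diff(tr$V)[up] < 2))
})

test_that("hold-and-release initializes at the clamped steady state", {
  p <- post_params
  st <- equilibrate_at_hold(p, -60)
  d <- csc_rhs(st, p)
  # all gate and calcium derivatives vanish when V is clamped
  expect_equal(unname(d[setdiff(state_names(), "V")]), rep(0, 7),
               tolerance = 1e-12)
  # at the calcium reversal no calcium flows
  st2 <- equilibrate_at_hold(p, p$E_Ca)
  expect_equal(st2[["Ca"]], 0)
})

test_that("alpha-function synaptic conductance has the documented shape", {
  g <- function(t) synaptic_conductance(t, peak = 2, tau = 5, onset = 10)
  expect_equal(g(15), 2)                      # maximum at onset + tau
  expect_equal(g(9.99), 0)
  expect_lt(g(14), g(15))
  expect_lt(g(16), g(15))
  quad <- integrate(g, 10, 400, rel.tol = 1e-10)
  expect_equal(quad$value, 2 * 5 * exp(1), tolerance = 1e-6)
})

test_that("synaptic protocol: enough excitation evokes a spike, inhibition delays it", {
  p <- post_params
  # start from a subthreshold hold so the input timing dominates
  base <- protocol_synaptic_pair(g_inh = 0, g_exc = 0.5, onset = 20)
  tr <- csc_simulate(p, 300, protocol = base,
                     init = equilibrate_at_hold(p, -72))
  lat_exc <- detect_spikes(tr)[1] - 20
  expect_true(is.finite(lat_exc))
  with_inh <- protocol_synaptic_pair(g_inh = 2, g_exc = 0.5, onset = 20,
                                     lag = 5)
  tr2 <- csc_simulate(p, 300, protocol = with_inh,
                      init = equilibrate_at_hold(p, -72))
  sp2 <- detect_spikes(tr2)
  lat_inh <- if (length(sp2)) sp2[1] - 20 else Inf
  expect_gt(lat_inh, lat_exc)
})

test_that("step protocol switches the applied current at t_step", {
  p <- post_params
  prot <- protocol_step(I_bias = -1, I_test = 1, t_step = 200)
  tr <- csc_simulate(p, 600, protocol = prot,
                     init = equilibrate_at_hold(p, -70))
  expect_equal(length(detect_spikes(tr[tr$t < 190, ])), 0)
  expect_gt(length(detect_spikes(tr[tr$t > 200, ])), 0)
})

test_that("the tonic action-potential cycle closes in the (V, dVdt) plane", {
  cyc <- phase_plane_cycle(tonic_post())
  expect_gt(nrow(cyc), 50)
  # nondegenerate loop area via the shoelace formula
  area <- abs(sum(cyc$V[-nrow(cyc)] * cyc$dVdt[-1] -
                    cyc$V[-1] * cyc$dVdt[-nrow(cyc)])) / 2
  expect_gt(area, 10)
  # rhs-based dVdt matches numerical differentiation of V
  mid <- 2:(nrow(cyc) - 1)
  num <- (cyc$V[mid + 1] - cyc$V[mid - 1]) /
    (cyc$t[mid + 1] - cyc$t[mid - 1])
  expect_equal(num, cyc$dVdt[mid], tolerance = 0.05)
})

test_that("trajectories round-trip through the trace format", {
  tr <- csc_simulate(post_params, 50, dt = 0.5)
  f <- tempfile(fileext = ".tsv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(as.data.frame(back)[, names(tr)], as.data.frame(tr),
               tolerance = 1e-12, ignore_attr = TRUE)
  p_back <- attr(back, "params")
  expect_equal(p_back$g_HVA, post_params$g_HVA)
  expect_equal(p_back$runup, "post")
  unlink(f)
})
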