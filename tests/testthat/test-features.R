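test_that("spike detection recovers surrogate construction exactly", {
  spec <- surrogate_spec(spikes_per_burst = c(7), noise_sd = 0)
  tr <- generate_surrogate_trace(spec)
  truth <- surrogate_truth(tr)
  det <- detect_spikes(tr)
  expect_length(det, 7)
  expect_equal(det, truth$spike_times, tolerance = 0.1)
  expect_length(detect_spikes(tibble::tibble(t = 1:100, V = rep(-60, 100))),
                0)
  expect_warning(detect_spikes(tibble::tibble(t = 1, V = -60)), "degenerate")
})

test_that("burst segmentation splits on gaps and keeps single-class trains whole", {
  sp <- c(0, 10, 20, 500, 510, 520)
  b <- segment_bursts(sp)
  expect_equal(nrow(b), 2)
  expect_equal(b$n_spikes, c(3L, 3L))
  # perfectly periodic train: one burst spanning the train
  b2 <- segment_bursts(seq(0, 900, by = 30))
  expect_equal(nrow(b2), 1)
  # generator pattern [4,4,4]
  tr <- generate_surrogate_trace(surrogate_spec(spikes_per_burst = c(4, 4, 4)))
  b3 <- segment_bursts(detect_spikes(tr))
  expect_equal(b3$n_spikes, c(4L, 4L, 4L))
})

test_that("spikes_per_burst returns the common count or flags non-periodicity", {
  tr <- generate_surrogate_trace(
    surrogate_spec(spikes_per_burst = rep(5L, 6)))
  expect_identical(spikes_per_burst(tr), 5L)
  tr2 <- generate_surrogate_trace(
    surrogate_spec(spikes_per_burst = c(5L, 3L, 5L, 3L, 5L, 3L, 5L, 3L)))
  out <- spikes_per_burst(tr2)
  expect_gt(length(out), 1)
  expect_false(isTRUE(attr(out, "periodic")))
  # tonic-like input signals absence of bursting
  flat <- tibble::tibble(t = seq(0, 5000, by = 0.5),
                         V = -60 + 50 * (sin(seq(0, 5000, by = 0.5) / 5) > 0.99))
  expect_error(spikes_per_burst(tonic_post()), "no bursting")
})

test_that("ISI return map separates periodic from alternating trains", {
  per <- isi_return_map(seq(0, 500, by = 25))
  expect_equal(attr(per, "dispersion"), 0)
  expect_true(all(per$isi_n == per$isi_np1))
  alt <- isi_return_map(cumsum(c(0, rep(c(10, 30), 10))))
  expect_gt(attr(alt, "dispersion"), 0)
  off <- alt[alt$isi_n != alt$isi_np1, ]
  # two mirror-symmetric off-diagonal clusters
  expect_setequal(unique(paste(off$isi_n, off$isi_np1)),
                  c("10 30", "30 10"))
  expect_error(isi_return_map(c(0, 10)), "at least 3")
})

test_that("first-spike latency uses the protocol onset and Inf sentinel", {
  p <- post_params
  prot <- protocol_hold_release(-75)
  tr <- csc_simulate(p, 1500, protocol = prot)
  lat <- first_spike_latency(tr)
  expect_true(is.finite(lat))
  expect_gt(lat, 0)
  # release into a non-spiking regime
  p_quiet <- csc_set(p, I_app = -2)
  tr2 <- csc_simulate(p_quiet, 800, protocol = protocol_hold_release(-75))
  expect_identical(first_spike_latency(tr2), Inf)
  expect_error(first_spike_latency(tonic_post()), "protocol")
})

test_that("first-spike latency is non-monotonic in the holding potential", {
  for (p in list(post_params, pre_params)) {
    holds <- seq(-100, -50, by = 5)
    lats <- vapply(holds, function(vh) {
      tr <- csc_simulate(p, 1200, protocol = protocol_hold_release(vh),
                         dt = 0.1)
      first_spike_latency(tr)
    }, 1)
    finite <- is.finite(lats)
    expect_gt(sum(finite), 5)
    lf <- lats[finite]
    # non-monotonic: an interior point beats both of its neighbours
    mid <- lf[-c(1, length(lf))]
    interior_max <- any(mid > head(lf, -2) & mid > tail(lf, -2))
    expect_true(interior_max)
  }
})

test_that("regime classification labels the canonical cases", {
  expect_identical(unclass(classify_regime(tonic_post()))[1], "T")
  # depolarization block: strong HVA with the system at a high fixed point
  ess <- csc_simulate(csc_set(post_params, g_HVA = 0.26), 6000, dt = 0.1)
  expect_identical(unclass(classify_regime(ess))[1], "ESS")
  # quiescent at a hyperpolarized fixed point
  q <- csc_simulate(csc_set(post_params, I_app = -2), 6000, dt = 0.1)
  expect_identical(unclass(classify_regime(q))[1], "Q")
  # fold/sub-Hopf bursting carries a depolarized spike-free plateau
  expect_identical(unclass(classify_regime(bursting_traj()))[1], "PB")
})

test_that("classification is stable under detector-threshold perturbation", {
  tr <- tonic_post()
  bt <- bursting_traj()
  for (thr in c(-22, -20, -18)) {
    expect_identical(unclass(classify_regime(tr, threshold = thr))[1], "T")
    expect_identical(unclass(classify_regime(bt, threshold = thr))[1], "PB")
  }
})

test_that("burst features assemble a coherent summary", {
  bf <- burst_features(bursting_traj())
  expect_s3_class(glance(bf), "tbl_df")
  expect_identical(bf$regime, "PB")
  expect_equal(sum(bf$spikes_per_burst), length(bf$spike_times))
  # active and silent intervals tile the spiking part of the window
  expect_equal(length(bf$silent_durations), nrow(bf$bursts) - 1)
  expect_true(all(bf$silent_durations > 0))
  td <- tidy(bf)
  expect_true(all(c("burst", "start", "end", "n_spikes") %in% names(td)))
})
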