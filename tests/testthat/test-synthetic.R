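test_that("surrogate generation is deterministic given the seed", {
  spec <- surrogate_spec(spikes_per_burst = c(3, 3), noise_sd = 1.5, seed = 7)
  tr1 <- generate_surrogate_trace(spec)
  tr2 <- generate_surrogate_trace(spec)
  expect_identical(tr1$V, tr2$V)
  tr3 <- generate_surrogate_trace(
    surrogate_spec(spikes_per_burst = c(3, 3), noise_sd = 1.5, seed = 8))
  expect_false(identical(tr1$V, tr3$V))
})

test_that("the generator does not disturb the global RNG stream", {
  set.seed(42)
  before <- runif(1)
  set.seed(42)
  invisible(generate_surrogate_trace(
    surrogate_spec(noise_sd = 1, seed = 99)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("spec invariants are enforced", {
  expect_error(surrogate_spec(intra_burst_isi = 10, inter_burst_gap = 25),
               "inter_burst_gap")
  expect_error(surrogate_spec(spikes_per_burst = integer(0)))
})

test_that("detection achieves F1 = 1 on surrogates up to 2 mV noise", {
  specs <- list(
    surrogate_spec(spikes_per_burst = c(14), noise_sd = 0),
    surrogate_spec(spikes_per_burst = c(5, 3, 5, 3), noise_sd = 1, seed = 2),
    surrogate_spec(spikes_per_burst = rep(4L, 5), noise_sd = 2, seed = 3),
    surrogate_spec(spikes_per_burst = c(6, 6, 6), plateau = TRUE,
                   amp_decay = 0.85, noise_sd = 2, seed = 4)
  )
  for (spec in specs) {
    tr <- generate_surrogate_trace(spec)
    truth <- surrogate_truth(tr)
    det <- detect_spikes(tr)
    expect_equal(spike_f1(det, truth$spike_times), 1)
    b <- segment_bursts(det)
    expect_equal(b$n_spikes, as.integer(truth$spikes_per_burst))
  }
})

test_that("pseudo-plateau surrogates are classified PB", {
  tr <- generate_surrogate_trace(
    surrogate_spec(spikes_per_burst = rep(5L, 12), plateau = TRUE,
                   plateau_duration = 150, amp_decay = 0.8,
                   inter_burst_gap = 500, noise_sd = 0))
  reg <- classify_regime(tr)
  expect_identical(unclass(reg)[1], "PB")
  # without the plateau the same construction reads as square-wave
  tr2 <- generate_surrogate_trace(
    surrogate_spec(spikes_per_burst = rep(5L, 12), plateau = FALSE,
                   inter_burst_gap = 500, noise_sd = 0))
  expect_identical(unclass(classify_regime(tr2))[1], "SW")
})

test_that("irregular-count surrogates are classified CB", {
  tr <- generate_surrogate_trace(
    surrogate_spec(spikes_per_burst = c(4, 7, 3, 9, 5, 8, 2, 6, 4, 7),
                   inter_burst_gap = 420, noise_sd = 0))
  expect_identical(unclass(classify_regime(tr))[1], "CB")
})

test_that("measurement noise on the model trace leaves spike counts intact", {
  p <- post_params
  clean <- csc_simulate(p, 2000)
  noisy <- generate_noisy_model_trace(p, 2000, noise_sd = 1, seed = 5)
  expect_identical(noisy$V_clean, clean$V)
  s_clean <- detect_spikes(clean)
  s_noisy <- detect_spikes(noisy)
  expect_equal(length(s_noisy), length(s_clean))
  expect_equal(spike_f1(s_noisy, s_clean), 1)
  zero <- generate_noisy_model_trace(p, 500, noise_sd = 0)
  expect_identical(zero$V, zero$V_clean)
})
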