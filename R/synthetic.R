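#' Specification of a surrogate burst trace
#'
#' Describes a ground-truth voltage trace emulating a whole-cell recording of
#' a bursting neuron: bursts of Gaussian-bump action potentials on a flat
#' baseline, optionally with decaying spike amplitudes running into a
#' depolarized plateau (pseudo-plateau morphology), plus additive Gaussian
#' measurement noise. The construction is deterministic given `seed`, and
#' the generator returns the true spike times and burst boundaries so the
#' feature-extraction stage can be validated without the model.
#'
#' @param spikes_per_burst integer vector, one entry per burst.
#' @param intra_burst_isi interspike interval within a burst (ms).
#' @param inter_burst_gap gap between the last spike of a burst and the first
#'   of the next (ms); must exceed `3 * intra_burst_isi` so the default
#'   segmenter can recover the construction.
#' @param amplitude spike amplitude above baseline (mV).
#' @param width spike full width (ms) of the Gaussian bump.
#' @param baseline resting level (mV).
#' @param plateau logical: append a depolarized plateau after each burst's
#'   last spike (with decaying spike amplitudes) for pseudo-plateau
#'   morphology.
#' @param plateau_duration plateau length (ms).
#' @param plateau_level plateau voltage (mV).
#' @param amp_decay per-spike multiplicative amplitude decay within a burst
#'   (1 = none); used by the pseudo-plateau morphology.
#' @param min_peak decaying spike amplitudes are floored so every peak
#'   reaches at least this voltage (mV), keeping every constructed spike
#'   above the default detection threshold.
#' @param noise_sd additive Gaussian noise SD (mV).
#' @param seed integer random seed for the noise.
#' @param dt sampling interval (ms).
#' @return a `surrogate_spec` list.
#' @export
surrogate_spec <- function(spikes_per_burst = c(4, 4, 4),
                           intra_burst_isi = 10, inter_burst_gap = 400,
                           amplitude = 70, width = 1.2, baseline = -62,
                           plateau = FALSE, plateau_duration = 150,
                           plateau_level = -30, amp_decay = 1,
                           min_peak = -15, noise_sd = 0, seed = 1,
                           dt = 0.05) {
  stopifnot(length(spikes_per_burst) >= 1, all(spikes_per_burst >= 1),
            intra_burst_isi > 0, amplitude > 0, width > 0, noise_sd >= 0)
  if (inter_burst_gap <= 3 * intra_burst_isi) {
    stop("inter_burst_gap must exceed 3 * intra_burst_isi")
  }
  structure(list(spikes_per_burst = as.integer(spikes_per_burst),
                 intra_burst_isi = intra_burst_isi,
                 inter_burst_gap = inter_burst_gap, amplitude = amplitude,
                 width = width, baseline = baseline, plateau = plateau,
                 plateau_duration = plateau_duration,
                 plateau_level = plateau_level, amp_decay = amp_decay,
                 min_peak = min_peak, noise_sd = noise_sd, seed = seed,
                 dt = dt),
            class = "surrogate_spec")
}

#' Generate a surrogate voltage trace with known ground truth
#'
#' @param spec a [surrogate_spec()].
#' @return a `csc_surrogate` tibble with columns `t`, `V`; the construction
#'   ground truth is attached as attribute `truth`: a list with
#'   `spike_times`, `bursts` (tibble of start/end/n_spikes) and
#'   `spikes_per_burst`.
#' @export
generate_surrogate_trace <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  lead <- 100
  spike_times <- list()
  plateaus <- list()
  t0 <- lead
  for (b in seq_along(spec$spikes_per_burst)) {
    n <- spec$spikes_per_burst[b]
    st <- t0 + spec$intra_burst_isi * (seq_len(n) - 1)
    spike_times[[b]] <- st
    t_end <- st[n]
    if (spec$plateau) {
      plateaus[[b]] <- c(t_end, t_end + spec$plateau_duration)
      t_end <- t_end + spec$plateau_duration
    }
    t0 <- t_end + spec$inter_burst_gap
  }
  total <- t0 + lead
  tt <- seq(0, total, by = spec$dt)
  v <- rep(spec$baseline, length(tt))
  sigma <- spec$width / 2.355          # FWHM -> SD
  for (b in seq_along(spike_times)) {
    for (k in seq_along(spike_times[[b]])) {
      amp <- max(spec$amplitude * spec$amp_decay^(k - 1),
                 spec$min_peak - spec$baseline)
      s <- spike_times[[b]][k]
      idx <- which(abs(tt - s) < 6 * sigma)
      v[idx] <- v[idx] + amp * exp(-(tt[idx] - s)^2 / (2 * sigma^2))
    }
    if (spec$plateau) {
      pl <- plateaus[[b]]
      idx <- which(tt >= pl[1] & tt <= pl[2])
      v[idx] <- pmax(v[idx], spec$plateau_level)
    }
  }
  if (spec$noise_sd > 0) {
    rs <- get_rng_state()
    on.exit(restore_rng_state(rs), add = TRUE)
    set.seed(spec$seed)
    v <- v + rnorm(length(v), sd = spec$noise_sd)
  }
  truth_bursts <- purrr::map_dfr(seq_along(spike_times), function(b) {
    st <- spike_times[[b]]
    tibble::tibble(burst = b, start = st[1], end = st[length(st)],
                   n_spikes = length(st))
  })
  out <- tibble::tibble(t = tt, V = v)
  attr(out, "truth") <- list(
    spike_times = unlist(spike_times),
    bursts = truth_bursts,
    spikes_per_burst = spec$spikes_per_burst
  )
  attr(out, "spec") <- spec
  class(out) <- c("csc_surrogate", class(out))
  out
}

#' Ground truth of a surrogate trace
#' @param trace a `csc_surrogate`.
#' @return the `truth` list attached by [generate_surrogate_trace()].
#' @export
surrogate_truth <- function(trace) attr(trace, "truth")

#' Model trace with additive measurement noise
#'
#' Simulates the model and adds Gaussian noise to the voltage column only —
#' measurement-noise emulation, not process noise (the model's irregular
#' bursting claims are noise-independent, so no stochastic terms enter the
#' dynamics).
#'
#' @inheritParams csc_simulate
#' @param noise_sd noise SD (mV).
#' @param seed integer seed.
#' @return a trajectory tibble; the clean voltage is kept as column `V_clean`.
#' @export
generate_noisy_model_trace <- function(params, duration, protocol = NULL,
                                       noise_sd = 1, seed = 1, ...) {
  traj <- csc_simulate(params, duration, protocol, ...)
  traj$V_clean <- traj$V
  if (noise_sd > 0) {
    rs <- get_rng_state()
    on.exit(restore_rng_state(rs), add = TRUE)
    set.seed(seed)
    traj$V <- traj$V + rnorm(nrow(traj), sd = noise_sd)
  }
  traj
}

#' F1 score of spike detection against ground truth
#'
#' Matches detections to true spike times greedily within `tol` ms and
#' returns the harmonic mean of precision and recall.
#'
#' @param detected,truth spike time vectors (ms).
#' @param tol matching tolerance (ms).
#' @return F1 in `[0, 1]`.
#' @export
spike_f1 <- function(detected, truth, tol = 2) {
  if (length(truth) == 0 && length(detected) == 0) return(1)
  if (length(truth) == 0 || length(detected) == 0) return(0)
  used <- rep(FALSE, length(detected))
  tp <- 0
  for (s in truth) {
    d <- abs(detected - s)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) { tp <- tp + 1; used[j] <- TRUE }
  }
  prec <- tp / length(detected)
  rec <- tp / length(truth)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
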