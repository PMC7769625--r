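#' Detect action potentials in a voltage trace
#'
#' A spike is the maximum of `V` within a supra-threshold excursion: the
#' segment between an upward and the following downward crossing of
#' `threshold`. Detections closer than `min_separation` are merged (the
#' higher peak wins). Works on any data frame with `t` and `V` columns
#' (trajectories, fast-subsystem trajectories, surrogate traces, bare
#' two-column recordings).
#'
#' @param trace data frame with columns `t` (ms) and `V` (mV).
#' @param threshold detection threshold (mV).
#' @param min_separation minimum inter-spike separation (ms).
#' @return numeric vector of spike times (ms); empty (with a warning) for
#'   degenerate traces.
#' @export
detect_spikes <- function(trace, threshold = -20, min_separation = 2) {
  if (is.null(trace) || nrow(trace) < 3) {
    warning("degenerate trace: no spikes detected")
    return(numeric(0))
  }
  v <- trace$V
  tt <- trace$t
  above <- v > threshold
  up <- which(!above[-length(above)] & above[-1]) + 1
  down <- which(above[-length(above)] & !above[-1])
  if (length(up) == 0) return(numeric(0))
  times <- numeric(0)
  for (u in up) {
    d <- down[down >= u]
    if (length(d) == 0) next  # unterminated excursion at trace end
    d <- d[1]
    seg <- u:d
    times <- c(times, tt[seg[which.max(v[seg])]])
  }
  if (length(times) > 1) {
    keep <- times[1]
    for (s in times[-1]) {
      if (s - keep[length(keep)] >= min_separation) keep <- c(keep, s)
    }
    times <- keep
  }
  times
}

#' Segment a spike train into bursts
#'
#' An inter-spike gap exceeding `gap_factor` times the median ISI splits
#' bursts. When no gap exceeds the cut (fewer than two gap classes) the whole
#' train is one burst, which the regime classifier maps to tonic firing.
#'
#' @param spike_times numeric vector of spike times (ms).
#' @param gap_factor multiple of the median ISI that defines a burst gap.
#' @return a tibble with one row per burst: `burst`, `start`, `end` (ms),
#'   `n_spikes`, and `spikes` (list column of spike times).
#' @export
segment_bursts <- function(spike_times, gap_factor = 3) {
  n <- length(spike_times)
  if (n == 0) {
    return(tibble::tibble(burst = integer(), start = numeric(),
                          end = numeric(), n_spikes = integer(),
                          spikes = list()))
  }
  if (n == 1) {
    return(tibble::tibble(burst = 1L, start = spike_times, end = spike_times,
                          n_spikes = 1L, spikes = list(spike_times)))
  }
  isi <- diff(spike_times)
  cut <- gap_factor * median(isi)
  grp <- cumsum(c(1L, as.integer(isi > cut)))
  purrr::map_dfr(split(spike_times, grp), function(s) {
    tibble::tibble(start = s[1], end = s[length(s)],
                   n_spikes = length(s), spikes = list(s))
  }) |>
    dplyr::mutate(burst = dplyr::row_number(), .before = 1)
}

#' Steady-state spikes per burst
#'
#' Extracts spikes from the post-transient analysis window, segments bursts,
#' discards the (possibly partial) first and last burst, and returns the
#' common spike count if the last three or more bursts agree. A non-repeating
#' count sequence is returned whole, flagged non-periodic.
#'
#' @param trajectory a [csc_simulate()] trajectory (or any `t`/`V` trace).
#' @param threshold,min_separation passed to [detect_spikes()].
#' @param gap_factor passed to [segment_bursts()].
#' @return an integer scalar (periodic burst count) or integer vector with
#'   attribute `periodic = FALSE`.
#' @export
spikes_per_burst <- function(trajectory, threshold = -20, min_separation = 2,
                             gap_factor = 3) {
  win <- analysis_window(trajectory)
  sp <- detect_spikes(win, threshold, min_separation)
  b <- segment_bursts(sp, gap_factor)
  if (nrow(b) < 2) stop("no bursting detected")
  counts <- b$n_spikes
  if (nrow(b) > 3) counts <- counts[-c(1, length(counts))]
  tailc <- tail(counts, 3)
  if (length(counts) >= 3 && length(unique(tailc)) == 1 &&
      all(tail(counts, min(length(counts), 5)) == tailc[1])) {
    return(tailc[1])
  }
  structure(counts, periodic = FALSE)
}

#' Interspike-interval return map
#'
#' Pairs of consecutive ISIs, with a dispersion statistic: the RMS distance
#' of the points from the identity diagonal, normalized by the mean ISI.
#' Periodic firing collapses onto the diagonal (dispersion 0); chaotic
#' bursting scatters points far off it.
#'
#' @param spike_times numeric vector of at least 3 spike times (ms).
#' @return a `csc_isi_map` tibble with columns `isi_n`, `isi_np1`; the
#'   dispersion is stored as attribute `dispersion` (see [glance.csc_isi_map]).
#' @export
isi_return_map <- function(spike_times) {
  if (length(spike_times) < 3) stop("need at least 3 spikes for a return map")
  isi <- diff(spike_times)
  out <- tibble::tibble(isi_n = isi[-length(isi)], isi_np1 = isi[-1])
  disp <- sqrt(mean((out$isi_np1 - out$isi_n)^2 / 2)) / mean(isi)
  attr(out, "dispersion") <- disp
  class(out) <- c("csc_isi_map", class(out))
  out
}

#' @export
glance.csc_isi_map <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x), dispersion = attr(x, "dispersion"),
                 mean_isi = mean(c(x$isi_n[1], x$isi_np1)))
}

#' First-spike latency after stimulus onset
#'
#' Time from the release (hold-and-release) or step onset to the first
#' detected spike; `Inf` when no spike occurs within the simulated window.
#'
#' @param trajectory a trajectory simulated under a `hold_release` or `step`
#'   protocol.
#' @param threshold,min_separation passed to [detect_spikes()].
#' @return latency (ms), possibly `Inf`.
#' @export
first_spike_latency <- function(trajectory, threshold = -20,
                                min_separation = 2) {
  prot <- traj_protocol(trajectory)
  if (is.null(prot) || !prot$kind %in% c("hold_release", "step")) {
    stop("first_spike_latency requires a hold_release or step protocol")
  }
  onset <- if (prot$kind == "step") prot$t_step else 0
  sp <- detect_spikes(trajectory, threshold, min_separation)
  sp <- sp[sp >= onset]
  if (length(sp) == 0) Inf else sp[1] - onset
}

#' Classify the dynamical regime of a trajectory
#'
#' Applies the package's operational decision rules to the post-transient
#' window:
#' * `ESS` — convergence to a fixed point above -40 mV (depolarization
#'   block);
#' * `Q`  — convergence to a fixed point at or below -40 mV;
#' * `T`  — spiking with a single inter-spike gap class (no burst
#'   structure);
#' * `CB` — bursting whose spikes-per-burst sequence does not repeat;
#' * `PB` — bursts ending in a spike-free depolarized plateau (at least
#'   `plateau_min_dur` ms above `plateau_level`) before repolarization;
#' * `SW` — repeating multi-spike bursts without such a plateau.
#'
#' The plateau level and duration are calibrated operational choices (the
#' literature separates square-wave from pseudo-plateau bursts by the
#' presence of the depolarized spike-free segment, without a quantitative
#' cutoff).
#'
#' @param trajectory a [csc_simulate()] trajectory.
#' @param threshold,min_separation spike detection settings.
#' @param gap_factor burst segmentation setting.
#' @param plateau_level minimum voltage of a plateau segment (mV).
#' @param plateau_min_dur minimum plateau duration (ms).
#' @return a `csc_regime` object: the label (character) with a `details`
#'   attribute (tibble of per-burst evidence).
#' @export
classify_regime <- function(trajectory, threshold = -20, min_separation = 2,
                            gap_factor = 3, plateau_level = -45,
                            plateau_min_dur = 20) {
  win <- analysis_window(trajectory)
  if (max(win$t) - min(win$t) < 1000) {
    stop("insufficient analysis window for classification")
  }
  v <- win$V
  tt <- win$t
  tail_idx <- tt > quantile(tt, 0.75)
  converged <- sd(v[tail_idx]) < 0.15 &&
    diff(range(v[tt > quantile(tt, 0.5)])) < 2
  sp <- detect_spikes(win, threshold, min_separation)
  if (converged || length(sp) == 0) {
    vf <- mean(v[tail_idx])
    label <- if (vf > -40) "ESS" else "Q"
    return(new_regime(label, tibble::tibble(final_V = vf,
                                            n_spikes = length(sp))))
  }
  b <- segment_bursts(sp, gap_factor)
  isi <- diff(sp)
  if (nrow(b) == 1) {
    # a single gap class covers both tonic firing and one-spike-per-cycle
    # plateau bursting; the depolarized spike-free segment separates them
    if (length(sp) >= 3) {
      pl <- vapply(head(sp, -1), function(s) {
        has_plateau(win, s, plateau_level, plateau_min_dur)
      }, logical(1))
      if (mean(pl) >= 0.5) {
        return(new_regime("PB", tibble::tibble(n_bursts = length(sp),
                                               counts = list(rep(1L, length(sp))),
                                               frac_plateau = mean(pl))))
      }
    }
    details <- tibble::tibble(n_spikes = length(sp),
                              isi_cv = sd(isi) / mean(isi))
    return(new_regime("T", details))
  }
  # complete bursts only (drop first/last, possibly clipped by the window)
  bc <- if (nrow(b) > 3) b[-c(1, nrow(b)), ] else b
  plateau <- vapply(seq_len(nrow(bc)), function(i) {
    has_plateau(win, bc$end[i], plateau_level, plateau_min_dur)
  }, logical(1))
  counts <- bc$n_spikes
  irregular <- length(counts) >= 4 && length(unique(counts)) > 1 &&
    !all(counts[-1] == counts[1])
  details <- tibble::tibble(n_bursts = nrow(bc),
                            counts = list(counts),
                            frac_plateau = mean(plateau))
  if (irregular && mean(plateau) < 0.5) return(new_regime("CB", details))
  if (mean(plateau) >= 0.5) return(new_regime("PB", details))
  if (irregular) return(new_regime("CB", details))
  new_regime("SW", details)
}

# a depolarized spike-free segment after the last spike of a burst and
# before repolarization below plateau_level
has_plateau <- function(win, burst_end, plateau_level, plateau_min_dur) {
  idx <- which(win$t > burst_end)
  if (length(idx) < 2) return(FALSE)
  below <- which(win$V[idx] < plateau_level)
  dur <- if (length(below) == 0) {
    win$t[idx[length(idx)]] - burst_end
  } else {
    win$t[idx[below[1]]] - burst_end
  }
  dur >= plateau_min_dur
}

new_regime <- function(label, details) {
  structure(label, details = details, class = "csc_regime")
}

#' @export
print.csc_regime <- function(x, ...) {
  names <- c(T = "tonic firing", SW = "square-wave bursting",
             PB = "pseudo-plateau bursting", CB = "chaotic bursting",
             ESS = "elevated steady state (depolarization block)",
             Q = "quiescent")
  cat("<csc_regime>", unclass(x), "-", names[[unclass(x)]], "\n")
  print(attr(x, "details"))
  invisible(x)
}

#' Extract one action-potential cycle in the (V, dV/dt) plane
#'
#' Takes a Poincare section at the upward crossing of `threshold`, extracts
#' the last full period from the analysis window, and attaches the phase
#' velocity computed from the model right-hand side (not from numerical
#' differentiation).
#'
#' @param trajectory a trajectory in a periodic spiking regime.
#' @param threshold section level (mV).
#' @param closure_tol maximum allowed start/end mismatch, as a fraction of
#'   the loop diameter.
#' @return a tibble `t`, `V`, `dVdt` covering one cycle.
#' @export
phase_plane_cycle <- function(trajectory, threshold = -20,
                              closure_tol = 0.01) {
  win <- analysis_window(trajectory)
  sp <- detect_spikes(win, threshold)
  if (length(sp) < 3) stop("non-periodic input: too few spikes")
  isi <- diff(sp)
  if (sd(isi) / mean(isi) > 0.05) {
    stop("non-periodic input: irregular interspike intervals")
  }
  v <- win$V
  above <- v > threshold
  up <- which(!above[-length(above)] & above[-1]) + 1
  if (length(up) < 2) stop("non-periodic input: fewer than two cycles")
  i0 <- up[length(up) - 1]
  i1 <- up[length(up)]
  cyc <- win[i0:i1, ]
  p <- traj_params(trajectory)
  cyc$dVdt <- vapply(seq_len(nrow(cyc)), function(i) {
    st <- unlist(cyc[i, state_names()])
    csc_rhs(st, p, t = cyc$t[i], protocol = traj_protocol(trajectory))[["V"]]
  }, 1)
  # closure check over (V, dVdt)
  d0 <- c(cyc$V[1], cyc$dVdt[1])
  d1 <- c(cyc$V[nrow(cyc)], cyc$dVdt[nrow(cyc)])
  diam <- sqrt(diff(range(cyc$V))^2 + diff(range(cyc$dVdt))^2)
  if (sqrt(sum((d1 - d0)^2)) > closure_tol * diam) {
    stop("cycle failed to close within tolerance")
  }
  cyc[, c("t", "V", "dVdt")]
}

#' Full burst-feature summary of a trajectory
#'
#' Runs spike detection, burst segmentation, the ISI return map and regime
#' classification on the post-transient window and assembles the results.
#'
#' @inheritParams classify_regime
#' @return a `csc_burst_features` list: `spike_times`, `bursts` (tibble),
#'   `spikes_per_burst`, `active_durations`, `silent_durations`, `isi_map`,
#'   `regime`, `mean_rate` (Hz). Has [tidy()] and [glance()] methods.
#' @export
burst_features <- function(trajectory, threshold = -20, min_separation = 2,
                           gap_factor = 3) {
  win <- analysis_window(trajectory)
  sp <- detect_spikes(win, threshold, min_separation)
  b <- segment_bursts(sp, gap_factor)
  dur <- max(win$t) - min(win$t)
  regime <- classify_regime(trajectory, threshold, min_separation, gap_factor)
  silent <- if (nrow(b) > 1) b$start[-1] - b$end[-nrow(b)] else numeric(0)
  out <- list(
    spike_times = sp,
    bursts = b,
    spikes_per_burst = b$n_spikes,
    active_durations = if (nrow(b)) b$end - b$start else numeric(0),
    silent_durations = silent,
    isi_map = if (length(sp) >= 3) isi_return_map(sp) else NULL,
    regime = unclass(regime)[1],
    mean_rate = 1000 * length(sp) / dur
  )
  class(out) <- "csc_burst_features"
  out
}

#' @export
print.csc_burst_features <- function(x, ...) {
  cat("<csc_burst_features>\n")
  cat("  regime:", x$regime, "  spikes:", length(x$spike_times),
      "  bursts:", nrow(x$bursts), "  mean rate:",
      sprintf("%.1f Hz", x$mean_rate), "\n")
  invisible(x)
}

#' @export
tidy.csc_burst_features <- function(x, ...) {
  dplyr::select(x$bursts, -"spikes")
}

#' @export
glance.csc_burst_features <- function(x, ...) {
  tibble::tibble(
    regime = x$regime,
    n_spikes = length(x$spike_times),
    n_bursts = nrow(x$bursts),
    mean_rate = x$mean_rate,
    isi_dispersion = if (is.null(x$isi_map)) NA_real_
                     else attr(x$isi_map, "dispersion")
  )
}
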