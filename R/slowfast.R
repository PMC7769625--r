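#' Critical manifold of the fast subsystem over the slow plane
#'
#' For every node of an (hA, Ca) grid, solves the fast-subsystem voltage
#' balance (all gates at steady state) for every root, labels each root's
#' stability from the 6x6 Jacobian, and assigns sheets: at a node with three
#' roots the lowest is the `lower` sheet, the intermediate the `middle`
#' (saddle) sheet and the highest the `upper` sheet; single roots are
#' assigned by voltage relative to the fold band. Fold curves (the loci
#' bounding the lower and upper sheets, where the root count changes) and
#' the Hopf locus on the upper sheet are extracted as polylines.
#'
#' @param params a [csc_params()] set.
#' @param hA_grid,Ca_grid monotone grids (defaults resolve the fold region
#'   at desk-scale cost).
#' @param V_range voltage search interval (mV).
#' @param n_V bracketing grid size per node.
#' @return a `csc_manifold` list: `sheet` (tibble `hA, Ca, V, sheet,
#'   stable, max_re`), `folds` (tibble `curve, Ca, hA` with curve `SN1` for
#'   the lower-sheet boundary and `SN2` for the upper), `hopf` (tibble
#'   `Ca, hA` where the upper sheet changes stability through a complex
#'   pair).
#' @export
compute_critical_manifold <- function(params,
                                      hA_grid = seq(0, 1, length.out = 201),
                                      Ca_grid = seq(0, 0.8, length.out = 81),
                                      V_range = c(-100, 10), n_V = 401) {
  stopifnot(!is.unsorted(hA_grid), !is.unsorted(Ca_grid))
  rows <- list()
  for (Ca in Ca_grid) {
    for (hA in hA_grid) {
      eq <- fast_equilibria(params, hA, Ca, V_range, n_V)
      if (nrow(eq) == 0) next
      ord <- order(eq$V)
      sheet <- if (nrow(eq) >= 3) {
        c("lower", "middle", "upper")[rank(eq$V)]
      } else rep(NA_character_, nrow(eq))
      rows[[length(rows) + 1]] <- tibble::tibble(
        hA = hA, Ca = Ca, V = eq$V, sheet = sheet, stable = eq$stable,
        max_re = eq$max_re, n_roots = nrow(eq),
        oscillatory = vapply(eq$eigenvalues,
                             function(ev) any(abs(Im(ev)) > 1e-7 &
                                                Re(ev) == max(Re(ev))),
                             logical(1)))
    }
  }
  sheet <- dplyr::bind_rows(rows)
  # label single roots by position relative to the 3-root band per Ca
  sheet <- dplyr::group_by(sheet, .data$Ca) |>
    dplyr::group_modify(function(df, key) {
      tri <- df[df$n_roots >= 3, ]
      if (nrow(tri) > 0) {
        vmid <- range(tri$V[tri$sheet == "middle"])
        single <- is.na(df$sheet)
        df$sheet[single] <- ifelse(df$V[single] > mean(vmid),
                                   "upper", "lower")
      } else {
        df$sheet[is.na(df$sheet)] <- ifelse(df$V[is.na(df$sheet)] > -50,
                                            "upper", "lower")
      }
      df
    }) |>
    dplyr::ungroup()

  folds <- dplyr::group_by(sheet, .data$Ca) |>
    dplyr::group_modify(function(df, key) {
      lower <- df$hA[df$sheet %in% c("lower", "middle")]
      upper <- df$hA[df$sheet %in% c("upper", "middle")]
      tri <- df$hA[df$n_roots >= 3]
      if (length(tri) == 0) {
        return(tibble::tibble(curve = character(), hA = numeric()))
      }
      tibble::tibble(curve = c("SN1", "SN2"),
                     hA = c(min(tri), max(tri)))
    }) |>
    dplyr::ungroup() |>
    dplyr::select("curve", "Ca", "hA")

  hopf <- dplyr::group_by(sheet[sheet$sheet == "upper", ], .data$Ca) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$hA), ]
      flip <- which(diff(sign(df$max_re)) != 0 &
                      (df$oscillatory[-1] | df$oscillatory[-nrow(df)]))
      tibble::tibble(hA = df$hA[flip])
    }) |>
    dplyr::ungroup() |>
    dplyr::select("Ca", "hA")

  structure(list(sheet = sheet, folds = folds, hopf = hopf,
                 params = params),
            class = "csc_manifold")
}

#' @export
print.csc_manifold <- function(x, ...) {
  cat(sprintf("<csc_manifold> %d nodes, %d Ca slices; sheets: %s\n",
              nrow(x$sheet), length(unique(x$sheet$Ca)),
              paste(sort(unique(x$sheet$sheet)), collapse = ", ")))
  cat(sprintf("fold points: %d (SN1), %d (SN2); Hopf points: %d\n",
              sum(x$folds$curve == "SN1"), sum(x$folds$curve == "SN2"),
              nrow(x$hopf)))
  invisible(x)
}

#' Bifurcation-set curves of the fast subsystem in the slow plane
#'
#' Assembles the loci of the fast-subsystem bifurcations over (hA, Ca): for
#' each Ca in the grid the saddle-node (fold) locations and the upper-sheet
#' Hopf location come from the equilibrium scan; optionally, periodic-orbit
#' continuation in hA contributes SNP/PD/homoclinic-approach loci on a
#' (typically coarser) subset of the Ca grid.
#'
#' @param params a [csc_params()] set.
#' @param Ca_grid calcium grid for the equilibrium-based curves.
#' @param po_Ca values at which to run periodic-orbit continuation (empty to
#'   skip); each needs a Hopf point on the upper sheet to seed from.
#' @param hA_range search range in hA.
#' @param ... further arguments to [continue_periodic_orbit()].
#' @return a tibble `curve, Ca, hA` (class `csc_bifset`) with curve labels
#'   `SN1`, `SN2`, `HB`, and (when orbit continuation ran) `SNP`, `PD`,
#'   `HC_approach`.
#' @export
bifurcation_set_2d <- function(params, Ca_grid = seq(0.05, 0.6, by = 0.025),
                               po_Ca = numeric(0), hA_range = c(0, 0.3),
                               ...) {
  man <- compute_critical_manifold(
    params,
    hA_grid = seq(hA_range[1], hA_range[2], length.out = 241),
    Ca_grid = Ca_grid, n_V = 301)
  curves <- dplyr::bind_rows(
    man$folds,
    dplyr::mutate(man$hopf, curve = "HB"))
  for (Ca in po_Ca) {
    hb <- man$hopf$hA[which.min(abs(man$hopf$Ca - Ca))]
    po_events <- tryCatch({
      seed <- po_from_hopf(params, hb, Ca)
      br <- continue_periodic_orbit(params, seed, Ca = Ca, ...)
      dplyr::bind_rows(attr(br, "events"), po_fold_events(br))
    }, error = function(e) NULL)
    if (!is.null(po_events) && nrow(po_events)) {
      curves <- dplyr::bind_rows(
        curves,
        tibble::tibble(curve = po_events$type, Ca = Ca, hA = po_events$hA))
    }
  }
  curves <- dplyr::arrange(curves, .data$curve, .data$Ca)
  class(curves) <- c("csc_bifset", class(curves))
  curves
}

#' Overlay a bursting trajectory on the slow-plane bifurcation structure
#'
#' Labels every sample of the post-transient window as belonging to an
#' active (spiking, padded to the surrounding sub-threshold crossings) or
#' silent phase, projects the trajectory to the (hA, Ca) plane, records its
#' crossings of the fold curves, and summarizes the slow-variable kinetics
#' (calcium rising during active phases and falling during silent ones for
#' fold/homoclinic-type bursts) plus the proximity of silent-phase samples
#' to the lower stable sheet.
#'
#' @param trajectory a bursting [csc_simulate()] trajectory.
#' @param manifold a [compute_critical_manifold()] result for the same
#'   parameters.
#' @param threshold spike threshold (mV).
#' @param pad_level sub-threshold level used to pad active phases (mV).
#' @return a `csc_overlay` list: `samples` (tibble with `t, V, hA, Ca,
#'   phase`), `crossings` (tibble of fold-curve crossings at burst onsets),
#'   `stats` (tibble: fraction of silent time within 2 mV of the lower
#'   sheet, sign of the mean Ca slope per phase).
#' @export
overlay_burst <- function(trajectory, manifold, threshold = -20,
                          pad_level = -45) {
  win <- analysis_window(trajectory)
  sp <- detect_spikes(win, threshold)
  b <- segment_bursts(sp)
  if (nrow(b) < 2) stop("trajectory is not bursting")

  phase <- rep("silent", nrow(win))
  below <- win$V < pad_level
  for (i in seq_len(nrow(b))) {
    i_first <- findInterval(b$start[i], win$t)
    i_last <- findInterval(b$end[i], win$t)
    j0 <- max(which(below[seq_len(max(i_first, 1))]), 1)
    after <- which(below & seq_len(nrow(win)) > i_last)
    j1 <- if (length(after)) min(after) else nrow(win)
    phase[j0:j1] <- "active"
  }
  samples <- tibble::tibble(t = win$t, V = win$V, hA = win$hA, Ca = win$Ca,
                            phase = phase)

  # fold crossings at each silent -> active transition
  fold_at <- function(curve, Ca) {
    f <- manifold$folds[manifold$folds$curve == curve, ]
    if (nrow(f) < 2) return(NA_real_)
    approx(f$Ca, f$hA, xout = Ca, rule = 2)$y
  }
  trans <- which(phase[-1] == "active" & phase[-length(phase)] == "silent")
  crossings <- purrr::map_dfr(trans, function(i) {
    tibble::tibble(t = samples$t[i], hA = samples$hA[i], Ca = samples$Ca[i],
                   d_SN1 = samples$hA[i] - fold_at("SN1", samples$Ca[i]),
                   d_SN2 = samples$hA[i] - fold_at("SN2", samples$Ca[i]))
  })

  # silent-phase proximity to the lower sheet
  lower <- manifold$sheet[manifold$sheet$sheet == "lower" &
                            manifold$sheet$stable, ]
  sil <- samples[samples$phase == "silent", ]
  near <- if (nrow(lower) > 3 && nrow(sil) > 0) {
    vapply(seq_len(nrow(sil)), function(i) {
      d <- abs(lower$hA - sil$hA[i]) / diff(range(manifold$sheet$hA)) +
        abs(lower$Ca - sil$Ca[i]) / max(diff(range(manifold$sheet$Ca)), 1e-9)
      abs(sil$V[i] - lower$V[which.min(d)]) <= 2
    }, logical(1))
  } else logical(0)

  ca_slope <- function(ph) {
    runs <- rle(samples$phase)
    ends <- cumsum(runs$lengths)
    starts <- c(1, head(ends, -1) + 1)
    idx <- which(runs$values == ph)
    # drop clipped first/last runs
    idx <- idx[idx > 1 & idx < length(runs$values)]
    if (length(idx) == 0) return(NA_real_)
    mean(vapply(idx, function(j) {
      s <- starts[j]:ends[j]
      samples$Ca[max(s)] - samples$Ca[min(s)]
    }, 1))
  }

  stats <- tibble::tibble(
    frac_silent_near_lower_sheet = if (length(near)) mean(near) else NA_real_,
    mean_dCa_active = ca_slope("active"),
    mean_dCa_silent = ca_slope("silent"),
    n_bursts = nrow(b))
  structure(list(samples = samples, crossings = crossings, stats = stats),
            class = "csc_overlay")
}

#' @export
print.csc_overlay <- function(x, ...) {
  cat("<csc_overlay>", nrow(x$samples), "samples,",
      x$stats$n_bursts, "bursts\n")
  print(as.data.frame(x$stats))
  invisible(x)
}
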