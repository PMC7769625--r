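#' Plot a voltage trajectory
#'
#' @param object a `csc_trajectory` (or fast trajectory / surrogate).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.csc_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$V)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "V (mV)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.csc_trajectory
#' @export
autoplot.csc_fast_trajectory <- autoplot.csc_trajectory

#' @rdname autoplot.csc_trajectory
#' @export
autoplot.csc_surrogate <- autoplot.csc_trajectory

#' Plot an equilibrium branch
#'
#' L2 norm of the state against the continuation parameter, solid for
#' stable and dotted for unstable segments, with detected saddle-node and
#' Hopf points marked.
#'
#' @param object a `csc_branch`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.csc_branch <- function(object, ...) {
  df <- tidy(object)
  ev <- branch_events(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$l2)) +
    ggplot2::geom_path(ggplot2::aes(linetype = .data$stable)) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dotted")) +
    ggplot2::labs(x = attr(object, "par_name"), y = "L2 norm",
                  linetype = "stable") +
    ggplot2::theme_minimal()
  if (nrow(ev)) {
    evdf <- dplyr::mutate(ev, l2 = approx(df$parameter, df$l2,
                                          xout = .data$par, rule = 2)$y)
    gg <- gg + ggplot2::geom_point(data = evdf,
                                   ggplot2::aes(x = .data$par, y = .data$l2),
                                   shape = 21, size = 2.5, fill = "white") +
      ggplot2::geom_text(data = evdf,
                         ggplot2::aes(x = .data$par, y = .data$l2,
                                      label = .data$type),
                         vjust = -1, size = 3)
  }
  gg
}

#' Plot a periodic-orbit branch
#'
#' Orbit voltage extrema against the continuation parameter, stability by
#' linetype.
#'
#' @param object a `csc_po_branch`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.csc_po_branch <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("V_min", "V_max"), names_to = "extreme",
                              values_to = "V")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$hA, y = .data$V,
                                     group = .data$extreme,
                                     linetype = .data$stable)) +
    ggplot2::geom_path() +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dotted")) +
    ggplot2::labs(x = "hA", y = "V (mV)") +
    ggplot2::theme_minimal()
}

#' Plot a regime map
#'
#' @param object a `csc_regime_map`.
#' @param fill `"regime"` (default) or `"n_spikes_per_burst"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.csc_regime_map <- function(object, fill = "regime", ...) {
  axes <- attr(object, "axes")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[axes[1]]], y = .data[[axes[2]]],
                               fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = axes[1], y = axes[2]) +
    ggplot2::theme_minimal()
}

#' Plot an ISI return map
#'
#' @param object a `csc_isi_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.csc_isi_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$isi_n, y = .data$isi_np1)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "ISI[n] (ms)", y = "ISI[n+1] (ms)") +
    ggplot2::theme_minimal()
}

#' Plot a slow-plane burst overlay
#'
#' The (hA, Ca) projection of the burst cycle colored by phase, over the
#' fold curves of the critical manifold.
#'
#' @param object a `csc_overlay`.
#' @param manifold optionally, the manifold whose folds to draw.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.csc_overlay <- function(object, manifold = NULL, ...) {
  gg <- ggplot2::ggplot(object$samples,
                        ggplot2::aes(x = .data$hA, y = .data$Ca,
                                     color = .data$phase)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::labs(x = "hA", y = "Ca (uM)") +
    ggplot2::theme_minimal()
  if (!is.null(manifold) && nrow(manifold$folds)) {
    gg <- gg + ggplot2::geom_path(
      data = manifold$folds,
      ggplot2::aes(x = .data$hA, y = .data$Ca, group = .data$curve),
      inherit.aes = FALSE, color = "black")
  }
  gg
}
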