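#' Two-parameter regime sweep with bistability probing
#'
#' Integrates the full system to steady behavior at every node of a
#' two-parameter grid and classifies the regime with [classify_regime()].
#' Cells are visited in serpentine order and each integration starts from
#' the previous cell's final state (attractor inheritance, the standard way
#' to follow bursting branches through bistable windows); an optional second
#' pass restarts every cell from a fixed default state, and cells where the
#' two passes disagree are flagged bistable. Failed integrations are
#' labelled `"failed"` and the sweep continues.
#'
#' @param params base [csc_params()] set.
#' @param axis1,axis2 lists `list(name = <parameter>, values = <grid>)`.
#' @param duration per-cell simulated time (ms).
#' @param two_pass run the fixed-initial-condition pass as well.
#' @param dt output sampling (ms).
#' @param ... further arguments to [classify_regime()].
#' @return a `csc_regime_map` tibble: one row per cell with the two
#'   parameter values, `regime`, `n_spikes_per_burst` (NA for non-bursting
#'   labels), `mean_rate`, and (when `two_pass`) `regime_fixed_ic` and
#'   `bistable`.
#' @export
regime_sweep <- function(params, axis1, axis2, duration = 12000,
                         two_pass = FALSE, dt = 0.1, ...) {
  stopifnot(is.list(axis1), is.list(axis2),
            length(axis1$values) >= 1, length(axis2$values) >= 1,
            length(axis1$values) * length(axis2$values) <= 200 * 200)
  grid <- expand.grid(i1 = seq_along(axis1$values),
                      i2 = seq_along(axis2$values))
  # serpentine order along axis1 within each axis2 row
  grid <- grid[order(grid$i2, ifelse(grid$i2 %% 2 == 0, -grid$i1, grid$i1)), ]

  run_cell <- function(p, init) {
    tryCatch({
      tr <- csc_simulate(p, duration, init = init, dt = dt)
      reg <- classify_regime(tr, ...)
      spb <- if (unclass(reg)[1] %in% c("SW", "PB")) {
        cnt <- tryCatch(spikes_per_burst(tr), error = function(e) NA)
        if (length(cnt) == 1) as.numeric(cnt) else round(mean(cnt))
      } else NA_real_
      sp <- detect_spikes(analysis_window(tr))
      list(regime = unclass(reg)[1], spb = spb,
           rate = 1000 * length(sp) / diff(range(analysis_window(tr)$t)),
           final = unlist(tr[nrow(tr), state_names()]))
    }, error = function(e) list(regime = "failed", spb = NA_real_,
                                rate = NA_real_, final = NULL))
  }

  default_init <- default_init_state(params)
  inherit <- NULL
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    p <- params
    p[[axis1$name]] <- axis1$values[grid$i1[r]]
    p[[axis2$name]] <- axis2$values[grid$i2[r]]
    res <- run_cell(p, if (is.null(inherit)) default_init else inherit)
    if (!is.null(res$final)) inherit <- res$final
    rows[[r]] <- tibble::tibble(
      !!axis1$name := axis1$values[grid$i1[r]],
      !!axis2$name := axis2$values[grid$i2[r]],
      regime = res$regime, n_spikes_per_burst = res$spb,
      mean_rate = res$rate, init = "inherited")
  }
  out <- dplyr::bind_rows(rows)

  if (two_pass) {
    fixed <- purrr::map_chr(seq_len(nrow(grid)), function(r) {
      p <- params
      p[[axis1$name]] <- axis1$values[grid$i1[r]]
      p[[axis2$name]] <- axis2$values[grid$i2[r]]
      run_cell(p, default_init)$regime
    })
    out$regime_fixed_ic <- fixed
    out$bistable <- out$regime != fixed
  }
  attr(out, "axes") <- c(axis1$name, axis2$name)
  attr(out, "params") <- params
  class(out) <- c("csc_regime_map", class(out))
  out
}

#' @export
print.csc_regime_map <- function(x, ...) {
  axes <- attr(x, "axes")
  cat(sprintf("<csc_regime_map> %d cells over (%s, %s)\n", nrow(x),
              axes[1], axes[2]))
  print(table(x$regime))
  invisible(x)
}

#' @export
glance.csc_regime_map <- function(x, ...) {
  tb <- table(factor(x$regime,
                     levels = c("T", "SW", "PB", "CB", "ESS", "Q", "failed")))
  out <- tibble::as_tibble(as.list(tb))
  names(out) <- paste0("n_", names(out))
  dplyr::mutate(out, n_cells = nrow(x), .before = 1)
}
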