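#' Named analysis configurations
#'
#' Ready-made configurations for [run_pipeline()] covering the package's
#' canonical analyses: the tonic presets, excitability scans, the bursting
#' parameter points, spikes-per-burst counts, the regime maps, the
#' fast-subsystem slice and the slow-plane curves.
#'
#' @param name one of `"tonic_post"`, `"tonic_pre"`, `"excitability"`,
#'   `"burst_low_gA"`, `"burst_default_gA"`, `"spike_counts"`,
#'   `"regime_map_gKCa_gA"`, `"fast_slice"`, `"slow_plane_curves"`,
#'   `"pseudo_plateau"`, `"chaotic_candidate"`, `"regime_map_gKCa_gHVA"`,
#'   `"high_gHVA"`.
#' @return a configuration list understood by [run_pipeline()].
#' @export
csc_config <- function(name) {
  cfgs <- list(
    tonic_post = list(preset = "post", stages = c("simulate", "features"),
                      duration = 4000),
    tonic_pre = list(preset = "pre", stages = c("simulate", "features"),
                     duration = 4000),
    excitability = list(preset = "post", stages = "snic"),
    burst_low_gA = list(preset = "post", set = list(g_HVA = 0.26, g_A = 6.0),
                        stages = c("simulate", "features"), duration = 16000),
    burst_default_gA = list(preset = "post", set = list(g_HVA = 0.235),
                            stages = c("simulate", "features"),
                            duration = 16000),
    spike_counts = list(preset = "post", stages = "spike_counts",
                        g_HVA_values = c(0.232, 0.253), duration = 16000),
    regime_map_gKCa_gA = list(
      preset = "post", set = list(g_HVA = 0.249), stages = "sweep",
      sweep = list(axis1 = list(name = "g_KCa", values = seq(1, 16, by = 3)),
                   axis2 = list(name = "g_A", values = c(10.2, 12.2)))),
    regime_map_gKCa_gHVA = list(
      preset = "post", set = list(g_A = 10.2), stages = "sweep",
      sweep = list(axis1 = list(name = "g_KCa",
                                values = c(0.5, 3, 7, 12)),
                   axis2 = list(name = "g_HVA",
                                values = c(0.1, 0.215, 0.4, 0.77)))),
    fast_slice = list(preset = "post", set = list(g_HVA = 0.249),
                      stages = "fast_slice", Ca = 0.25),
    slow_plane_curves = list(preset = "post", set = list(g_HVA = 0.249),
                             stages = "slow_plane",
                             Ca_grid = seq(0.1, 0.5, by = 0.05)),
    pseudo_plateau = list(preset = "post",
                          set = list(g_K = 12, g_KCa = 7, g_HVA = 0.22),
                          stages = c("simulate", "features"),
                          duration = 16000),
    chaotic_candidate = list(preset = "post",
                             set = list(g_KCa = 3, g_HVA = 0.215),
                             stages = c("simulate", "features"),
                             duration = 16000),
    high_gHVA = list(preset = "post", set = list(g_HVA = 0.77),
                     stages = c("simulate", "features"), duration = 16000)
  )
  if (!name %in% names(cfgs)) {
    stop("unknown config '", name, "'; available: ",
         paste(names(cfgs), collapse = ", "))
  }
  c(cfgs[[name]], list(name = name))
}

#' Run an analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order and returns an artifact
#' bundle. Unknown parameter names in `config$set` are rejected; the fully
#' resolved configuration travels with the bundle. A stage failure marks the
#' bundle partial and skips downstream stages. Rerunning an identical
#' configuration reproduces identical outputs (the pipeline is
#' deterministic).
#'
#' @param config a list as produced by [csc_config()]:
#'   `preset` (`"post"`/`"pre"`), optional `set` (named parameter
#'   overrides), `stages` (subset of `"simulate"`, `"features"`,
#'   `"spike_counts"`, `"sweep"`, `"snic"`, `"fast_slice"`,
#'   `"slow_plane"`), plus stage-specific fields (`duration`, `sweep`,
#'   `Ca`, `Ca_grid`, `g_HVA_values`).
#' @param out optional directory: trajectory/branch/map artifacts are also
#'   written there as delimited text.
#' @return a `csc_bundle` list with one element per executed stage plus
#'   `config` (resolved), `partial` (logical), and `errors`.
#' @export
run_pipeline <- function(config, out = NULL) {
  stopifnot(is.list(config))
  params <- do.call(csc_params,
                    c(list(runup = config$preset %||% "post"),
                      config$set %||% list()))
  stages <- config$stages %||% character(0)
  bundle <- list(config = c(config, list(resolved_params = tidy(params))),
                 partial = FALSE, errors = list())
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(bundle, stage, f) {
    if (bundle$partial) return(bundle)
    res <- tryCatch(f(), error = function(e) e)
    if (inherits(res, "error")) {
      bundle$partial <- TRUE
      bundle$errors[[stage]] <- conditionMessage(res)
    } else {
      bundle[[stage]] <- res
    }
    bundle
  }

  for (stage in stages) {
    bundle <- switch(
      stage,
      simulate = run_stage(bundle, "trajectory", function() {
        tr <- csc_simulate(params, config$duration %||% 4000)
        if (!is.null(out)) write_trace(tr, file.path(out, "trajectory.tsv"))
        tr
      }),
      features = run_stage(bundle, "features", function() {
        if (is.null(bundle$trajectory)) stop("features stage needs simulate")
        burst_features(bundle$trajectory)
      }),
      spike_counts = run_stage(bundle, "spike_counts", function() {
        purrr::map_dfr(config$g_HVA_values, function(g) {
          tr <- csc_simulate(csc_set(params, g_HVA = g),
                             config$duration %||% 16000, dt = 0.1)
          cnt <- tryCatch(spikes_per_burst(tr), error = function(e) NA)
          tibble::tibble(g_HVA = g,
                         spikes_per_burst = if (length(cnt) == 1)
                           as.numeric(cnt) else NA_real_,
                         periodic = length(cnt) == 1)
        })
      }),
      sweep = run_stage(bundle, "regime_map", function() {
        sw <- config$sweep
        m <- regime_sweep(params, sw$axis1, sw$axis2,
                          duration = config$duration %||% 12000)
        if (!is.null(out)) {
          write_table_with_events(m, file.path(out, "regime_map.tsv"))
        }
        m
      }),
      snic = run_stage(bundle, "snic", function() classify_snic(params)),
      fast_slice = run_stage(bundle, "fast_slice", function() {
        continue_equilibria(params, "hA", c(0, 0.3), fast = TRUE,
                            Ca = config$Ca %||% 0.25, start_V = -75)
      }),
      slow_plane = run_stage(bundle, "slow_plane", function() {
        cv <- bifurcation_set_2d(params,
                                 Ca_grid = config$Ca_grid %||%
                                   seq(0.1, 0.5, by = 0.05))
        if (!is.null(out)) {
          utils::write.table(as.data.frame(cv),
                             file.path(out, "slow_plane_curves.tsv"),
                             sep = "\t", row.names = FALSE, quote = FALSE)
        }
        cv
      }),
      stop("unknown stage '", stage, "'")
    )
  }
  class(bundle) <- "csc_bundle"
  bundle
}

#' @export
print.csc_bundle <- function(x, ...) {
  cat("<csc_bundle>", if (x$partial) "(partial)" else "(complete)", "\n")
  cat("stages:", paste(setdiff(names(x), c("config", "partial", "errors")),
                       collapse = ", "), "\n")
  if (length(x$errors)) {
    for (nm in names(x$errors)) cat("error in", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
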