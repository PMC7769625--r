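#' Write and read trajectory tables
#'
#' Trajectories are stored as tab-delimited text with a `#`-prefixed header
#' block carrying the column list, units, and the resolved parameter set, so
#' a written file is self-describing and reads back equal to the in-memory
#' object.
#'
#' @param traj a trajectory tibble (full, fast, or surrogate).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# columns: %s", paste(names(traj), collapse = " ")), con)
  writeLines("# units: t ms; V mV; gates dimensionless; Ca uM", con)
  p <- attr(traj, "params")
  if (!is.null(p)) {
    nm <- setdiff(names(p), "runup")
    writeLines(sprintf("# param %s = %s", c(nm, "runup"),
                       c(vapply(p[nm], format, ""), p$runup)), con)
  }
  utils::write.table(as.data.frame(traj), con, sep = "\t",
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param path file written by [write_trace()] (or bare two-column `t V`
#'   text for external recordings).
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  df <- utils::read.table(text = lines[!hdr], header = any(grepl("^t\\b", lines[!hdr])) ||
                            TRUE, sep = "", check.names = FALSE)
  out <- tibble::as_tibble(df)
  pl <- lines[grepl("^# param ", lines)]
  if (length(pl)) {
    kv <- sub("^# param ", "", pl)
    keys <- sub(" = .*$", "", kv)
    vals <- sub("^.* = ", "", kv)
    p <- as.list(suppressWarnings(as.numeric(vals)))
    names(p) <- keys
    if ("runup" %in% keys) p$runup <- vals[keys == "runup"]
    attr(out, "params") <- structure(p, class = "csc_params")
  }
  out
}

#' Write a continuation branch or regime map as delimited text
#'
#' One row per branch point or grid cell; events are appended as a
#' `#`-prefixed summary block.
#'
#' @param x a `csc_branch`, `csc_po_branch` or `csc_regime_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_with_events <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  df <- if (inherits(x, "csc_branch") || inherits(x, "csc_po_branch")) {
    tidy(x)
  } else {
    as.data.frame(x)[, !vapply(x, is.list, logical(1))]
  }
  ev <- attr(x, "events")
  if (!is.null(ev) && nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      writeLines(sprintf("# event %s", paste(names(ev),
                                             unlist(ev[i, ]), sep = "=",
                                             collapse = " ")), con)
    }
  }
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
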