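#' Read a run or sweep configuration file
#'
#' Configurations are JSON (or YAML, if the \pkg{yaml} package is
#' available) objects whose keys are [model_params()] fields; `n_cells`
#' is required, everything else falls back to the documented defaults.
#' A `sweep` sub-object with keys `param`, `values` and optionally
#' `reps` turns the result into a [sweep_spec()].
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `model_params` or `sweep_spec` object.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sweep_part <- raw$sweep
  raw$sweep <- NULL
  known <- names(formals(model_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!"n_cells" %in% names(raw)) {
    stop("config schema violation: required field 'n_cells' is missing")
  }
  params <- do.call(model_params, raw)
  if (is.null(sweep_part)) return(params)
  if (!all(c("param", "values") %in% names(sweep_part))) {
    stop("config schema violation: sweep needs fields 'param' and 'values'")
  }
  sweep_spec(sweep_part$param, unlist(sweep_part$values),
             reps = if (is.null(sweep_part$reps)) 10L else sweep_part$reps,
             base = params)
}

#' Write a configuration file
#'
#' Round-trip stable with [load_config()]: saving and re-loading yields
#' an identical object.
#'
#' @param x A `model_params` or `sweep_spec` object.
#' @param path Destination (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(x, path) {
  obj <- if (inherits(x, "sweep_spec")) {
    c(unclass(x$base),
      list(sweep = list(param = x$param, values = x$values, reps = x$reps)))
  } else {
    unclass(x)
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("writing YAML configs requires the 'yaml' package")
    }
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Write the outputs of a run or sweep to disk
#'
#' For a trajectory: `frames.csv` (t, cell, x, y, alpha, r),
#' `junctions.csv` (t, i, end_i, j, end_j, type) and `run.json`
#' (parameters, seed, event counts). For a sweep: the per-run and
#' summary tables plus the spec.
#'
#' @param x A `cell_traj` or `cell_sweep` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_outputs <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "cell_traj")) {
    write.csv(x$frames, file.path(out_dir, "frames.csv"), row.names = FALSE)
    write.csv(x$junctions, file.path(out_dir, "junctions.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(params = unclass(x$params), seed = x$seed,
           events = as.list(x$events)),
      file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE
    )
  } else if (inherits(x, "cell_sweep")) {
    write.csv(x$runs, file.path(out_dir, "sweep_runs.csv"),
              row.names = FALSE)
    write.csv(tidy(x), file.path(out_dir, "sweep_summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(param = x$spec$param, values = x$spec$values,
           reps = x$spec$reps, base = unclass(x$spec$base)),
      file.path(out_dir, "sweep_spec.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE
    )
  } else {
    stop("write_outputs() handles cell_traj and cell_sweep objects")
  }
  invisible(out_dir)
}

#' Export a junction graph as GraphML
#'
#' @param jg A [junction_graph()] result.
#' @param path Destination `.graphml` file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(jg, path) {
  igraph::write_graph(jg$graph, path, format = "graphml")
  invisible(path)
}
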