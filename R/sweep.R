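#' Specify a parameter sweep
#'
#' Describes an ensemble experiment: one model parameter varied over a
#' grid, with `reps` independent replicates (random initial conditions)
#' per grid value. Replicate `k` uses seed `base$seed + k - 1` at every
#' grid value, so grid values are compared on a common set of initial
#' conditions.
#'
#' @param param Name of the varied [model_params()] field (e.g. `"nu"`,
#'   `"kappa"`, `"lam"`, `"gamma"`, `"r0"`).
#' @param values Non-empty numeric grid.
#' @param reps Replicates per grid value (default 10).
#' @param base Base parameter set; defaults to the reduced-scale
#'   junction-free base model.
#' @param scale Optional rescaling applied to `base`: `"none"` or
#'   `"reduced"` (see [reduced_scale()]).
#' @return An object of class `sweep_spec`.
#' @examples
#' sweep_spec("nu", c(0.1, 0.2, 0.5), reps = 3,
#'            base = model_params(n_cells = 20, box_l = 8, t_end = 10))
#' @export
sweep_spec <- function(param, values, reps = 10,
                       base = reduced_scale(model_params()),
                       scale = c("none", "reduced")) {
  scale <- match.arg(scale)
  stopifnot(is.character(param), length(param) == 1, length(values) >= 1,
            reps >= 1)
  if (!param %in% names(base)) stop("unknown parameter: ", param)
  if (scale == "reduced") base <- reduced_scale(base)
  structure(list(param = param, values = as.numeric(values),
                 reps = as.integer(reps), base = base),
            class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat(sprintf("<sweep_spec> %s in {%s}, %d replicates, base seed %d\n",
              x$param, paste(signif(x$values, 4), collapse = ", "),
              x$reps, x$base$seed))
  invisible(x)
}

#' Run a parameter sweep
#'
#' Simulates every (grid value, replicate) combination and records the
#' equilibrated alignment plus cheap per-run observables. Results are
#' reproducible bit-for-bit from the spec (seeds are derived from the
#' base seed).
#'
#' @param spec A [sweep_spec()] object.
#' @param eq_frac Final fraction of frames over which alignment is
#'   averaged (default 0.1).
#' @param keep_trajectories Keep the full `cell_traj` objects (memory
#'   heavy; default `FALSE`).
#' @param out_dir Optional directory; when given, the per-run table and
#'   its summary are written as CSV.
#' @param .progress Print one line per grid value.
#' @return An object of class `cell_sweep`: a list with `runs` (tibble
#'   `value`, `rep`, `seed`, `alignment`, `mean_r`, `n_junctions`,
#'   `pct_degree_0/1/2`, event counts), `spec`, and optionally
#'   `trajectories`.
#' @export
run_sweep <- function(spec, eq_frac = 0.1, keep_trajectories = FALSE,
                      out_dir = NULL, .progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  base <- spec$base
  grid <- tidyr::expand_grid(value = spec$values, rep = seq_len(spec$reps))
  trajs <- if (keep_trajectories) vector("list", nrow(grid)) else NULL
  rows <- purrr::pmap(list(grid$value, grid$rep, seq_len(nrow(grid))),
                      function(v, k, idx) {
    args <- setNames(list(v, as.integer(base$seed + k - 1)),
                     c(spec$param, "seed"))
    p <- do.call(update_params, c(list(base), args))
    tr <- tryCatch(simulate_cells(p), error = function(e) {
      stop("replicate failed (", spec$param, " = ", v, ", seed = ",
           base$seed + k - 1, "): ", conditionMessage(e), call. = FALSE)
    })
    if (keep_trajectories) trajs[[idx]] <<- tr
    cells <- get_frame(tr)
    jn <- get_junctions(tr)
    jg <- junction_graph(cells, jn)
    if (.progress && k == spec$reps) {
      message(sprintf("%s = %g done", spec$param, v))
    }
    tibble::tibble(
      value = v, rep = k, seed = p$seed,
      alignment = equilibrated_alignment(tr, eq_frac),
      alignment_final = nematic_alignment(cells),
      mean_r = mean(cells$r),
      n_junctions = nrow(jn),
      pct_degree_0 = 100 * degree_fraction(jg, 0),
      pct_degree_1 = 100 * degree_fraction(jg, 1),
      pct_degree_2 = 100 * degree_fraction(jg, 2),
      containment_events = as.integer(tr$events[["containment"]]),
      clamp_hi_events = as.integer(tr$events[["clamp_hi"]]),
      jitter_events = as.integer(tr$events[["jitter"]])
    )
  })
  out <- structure(
    list(runs = dplyr::bind_rows(rows), spec = spec, trajectories = trajs),
    class = "cell_sweep"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out$runs, file.path(out_dir, "sweep_runs.csv"),
              row.names = FALSE)
    write.csv(tidy(out), file.path(out_dir, "sweep_summary.csv"),
              row.names = FALSE)
  }
  out
}

#' @export
print.cell_sweep <- function(x, ...) {
  cat(sprintf("<cell_sweep> %s over %d values x %d replicates\n",
              x$spec$param, length(x$spec$values), x$spec$reps))
  print(tidy(x))
  invisible(x)
}

#' @rdname run_sweep
#' @param x A `cell_sweep` object.
#' @param ... Unused.
#' @return `tidy()`: one row per grid value with the ensemble mean and
#'   standard deviation of the equilibrated alignment and of the other
#'   recorded observables.
#' @export
tidy.cell_sweep <- function(x, ...) {
  x$runs |>
    dplyr::group_by(value = .data$value) |>
    dplyr::summarise(
      mean_alignment = mean(.data$alignment),
      sd_alignment = sd(.data$alignment),
      mean_r = mean(.data$mean_r),
      mean_n_junctions = mean(.data$n_junctions),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' @rdname run_sweep
#' @return `glance()`: a one-row tibble with the grid value maximising
#'   the mean equilibrated alignment (`argmax_value`), that maximum, and
#'   the run count.
#' @export
glance.cell_sweep <- function(x, ...) {
  s <- tidy(x)
  tibble::tibble(
    param = x$spec$param,
    argmax_value = s$value[which.max(s$mean_alignment)],
    max_mean_alignment = max(s$mean_alignment),
    n_values = nrow(s),
    n_runs = nrow(x$runs)
  )
}
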