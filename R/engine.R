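#' Random initial population
#'
#' Places `n_cells` cells uniformly at random in the box with uniform
#' random orientations and aspect ratio `r0`, reproducibly from
#' `params$seed` (the caller's RNG state is left untouched).
#'
#' @param params A [model_params()] object.
#' @return A [cell_population()] tibble.
#' @export
init_population <- function(params) {
  withr::with_seed(params$seed, random_population(params))
}

random_population <- function(params) {
  n <- params$n_cells
  cell_population(
    x = runif(n, 0, params$box_l), y = runif(n, 0, params$box_l),
    alpha = runif(n, 0, 2 * pi), r = params$r0
  )
}

#' Broad-phase neighbour candidates
#'
#' Returns every unordered cell pair whose minimum-image centroid
#' distance is below the sum of their bounding-circle radii
#' (`a_i + a_j`): a cheap superset of all actually overlapping pairs.
#'
#' @param cells A [cell_population()] tibble.
#' @param box_l Periodic box side.
#' @return A tibble with columns `i` and `j` (`i < j`).
#' @export
neighbor_candidates <- function(cells, box_l = Inf) {
  m <- cpp_pairs(cells$x, cells$y, cells$alpha, cells$r, box_l, 0L)
  tibble::tibble(i = m[, 1], j = m[, 2])
}

#' Pairs of cells that actually overlap
#'
#' Narrow-phase check: pairs whose boundaries cross, or where one cell
#' contains the other.
#'
#' @inheritParams neighbor_candidates
#' @return A tibble with columns `i` and `j` (`i < j`).
#' @export
overlapping_pairs <- function(cells, box_l = Inf) {
  m <- cpp_pairs(cells$x, cells$y, cells$alpha, cells$r, box_l, 1L)
  tibble::tibble(i = m[, 1], j = m[, 2])
}

#' One explicit-Euler step
#'
#' Advances the population by one time step: all derivatives are
#' evaluated at the current state (simultaneous update), positions are
#' wrapped into `[0, L)`, orientations into `[0, 2*pi)`, and aspect
#' ratios (when shape dynamics are active) are clamped to `[1, 16]`.
#'
#' @param cells A [cell_population()] tibble.
#' @param params A [model_params()] object.
#' @return The updated `cell_population` tibble.
#' @export
sim_step <- function(cells, params) {
  d <- model_rhs(cells, params)
  out <- cells
  out$x <- (cells$x + params$dt * d$dx) %% params$box_l
  out$y <- (cells$y + params$dt * d$dy) %% params$box_l
  out$alpha <- wrap_angle(cells$alpha + params$dt * d$dalpha)
  if (params$shape_on) {
    out$r <- pmin(pmax(cells$r + params$dt * d$dr, 1), 16)
  }
  out
}

#' Simulate a cell population
#'
#' Integrates the full model with an explicit Euler scheme from `t = 0`
#' to `t = t_end`, recording frame 0 and every `save_every`-th step.
#' The run is deterministic given `params` (including the seed, which
#' drives the initial condition and any degeneracy-resolving jitter).
#'
#' @param params A [model_params()] object.
#' @param init Optional initial [cell_population()]; by default one is
#'   drawn from `params$seed` as in [init_population()].
#' @return An object of class `cell_traj`: a list with `frames` (tibble
#'   `t`, `cell`, `x`, `y`, `alpha`, `r`), `junctions` (tibble `t`, `i`,
#'   `end_i`, `j`, `end_j`, `type`; active junctions at each saved frame
#'   when the junction module is on), `params`, `events` (named counts of
#'   containment fallbacks, aspect-ratio clamps and degeneracy jitters)
#'   and `seed`.
#' @examples
#' p <- model_params(nu = 0.2, n_cells = 12, box_l = 8, t_end = 1, seed = 4)
#' traj <- simulate_cells(p)
#' glance(traj)
#' @export
simulate_cells <- function(params, init = NULL) {
  validate_params(params)
  nsteps <- round(params$t_end / params$dt)
  if (abs(nsteps * params$dt - params$t_end) > 1e-9) {
    stop("t_end must be an integer multiple of dt")
  }
  run <- function() {
    state <- if (is.null(init)) random_population(params) else init
    res <- cpp_simulate(
      state$x, state$y, state$alpha, state$r,
      params$nu, params$gamma, params$rbar, params$kappa, params$mu,
      params$lam, params$box_l, params$dt, nsteps, params$save_every,
      params$shape_on, params$junctions_on, params$noise_sd
    )
    res
  }
  res <- withr::with_seed(params$seed, run())

  n <- params$n_cells
  nframes <- length(res$times)
  frames <- tibble::tibble(
    t = rep(res$times, each = n),
    cell = rep.int(seq_len(n), nframes),
    x = as.vector(t(res$x)), y = as.vector(t(res$y)),
    alpha = as.vector(t(res$alpha)), r = as.vector(t(res$r))
  )
  jm <- res$junctions
  junctions <- tibble::tibble(
    t = jm[, 1], i = as.integer(jm[, 2]),
    end_i = ifelse(jm[, 3] > 0, "front", "back"),
    j = as.integer(jm[, 4]),
    end_j = ifelse(jm[, 5] > 0, "front", "back"),
    type = ifelse(jm[, 6] == 1, "fb", "ffbb")
  )
  structure(
    list(frames = frames, junctions = junctions, params = params,
         events = res$events, seed = params$seed),
    class = "cell_traj"
  )
}

#' Extract one frame of a trajectory as a population state
#'
#' @param traj A `cell_traj` object.
#' @param t A recorded time, or `"last"`/`"first"`.
#' @return A [cell_population()] tibble (with the frame time as
#'   attribute `t`).
#' @export
get_frame <- function(traj, t = "last") {
  times <- unique(traj$frames$t)
  tt <- if (identical(t, "last")) {
    max(times)
  } else if (identical(t, "first")) {
    0
  } else {
    times[which.min(abs(times - t))]
  }
  fr <- dplyr::filter(traj$frames, abs(.data$t - tt) < 1e-9)
  out <- tibble::tibble(cell = fr$cell, x = fr$x, y = fr$y,
                        alpha = fr$alpha, r = fr$r)
  attr(out, "t") <- tt
  out
}

#' Active junctions at one recorded frame
#'
#' @inheritParams get_frame
#' @return A tibble of junction rows at that frame.
#' @export
get_junctions <- function(traj, t = "last") {
  tt <- attr(get_frame(traj, t), "t")
  dplyr::filter(traj$junctions, abs(.data$t - tt) < 1e-9)
}

#' @export
print.cell_traj <- function(x, ...) {
  cat(sprintf(
    "<cell_traj> N = %d, L = %g, T = %g (%d frames), final alignment = %.3f\n",
    x$params$n_cells, x$params$box_l, x$params$t_end,
    length(unique(x$frames$t)), nematic_alignment(get_frame(x))
  ))
  ev <- x$events
  if (any(ev > 0)) {
    cat("  events:", paste(names(ev), ev, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @rdname simulate_cells
#' @param x A `cell_traj` object.
#' @param ... Unused.
#' @export
tidy.cell_traj <- function(x, ...) x$frames

#' @rdname simulate_cells
#' @export
glance.cell_traj <- function(x, ...) {
  last <- get_frame(x)
  tibble::tibble(
    n_cells = x$params$n_cells, box_l = x$params$box_l,
    t_end = x$params$t_end, n_frames = length(unique(x$frames$t)),
    alignment_final = nematic_alignment(last),
    alignment_eq = equilibrated_alignment(x),
    mean_r_final = mean(last$r),
    n_junctions_final = nrow(get_junctions(x)),
    containment_events = as.integer(x$events[["containment"]]),
    clamp_events = as.integer(x$events[["clamp_lo"]] + x$events[["clamp_hi"]]),
    jitter_events = as.integer(x$events[["jitter"]])
  )
}
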