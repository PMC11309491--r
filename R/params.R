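#' Model parameters and run controls
#'
#' Collects the non-dimensional constants of the cell-alignment model and
#' the controls of a single simulation run. Lengths are measured in units
#' of the reference length `sqrt(A/pi)` (so every cell has area `pi`) and
#' time in units of the overlap-relaxation time, which makes every
#' parameter below a dimensionless group.
#'
#' @param nu Self-propulsion speed relative to overlap avoidance
#'   (`nu >= 0`). `nu = 0` gives passive, purely overlap-driven cells.
#' @param gamma Shape-restoring strength (`gamma >= 0`). `gamma > 0`
#'   activates aspect-ratio dynamics unless `shape_on` is forced off.
#' @param rbar Preferred aspect ratio towards which deformable cells
#'   relax (`rbar > 1`, default 2).
#' @param kappa Cell-cell junction spring strength relative to overlap
#'   avoidance (`kappa >= 0`).
#' @param mu Supracellular actin bending strength relative to overlap
#'   avoidance (`mu >= 0`).
#' @param lam Junction formation/breakage range (non-dimensional length,
#'   `lam >= 0`).
#' @param n_cells Number of cells `N`.
#' @param box_l Side length `L` of the periodic square box.
#' @param dt Explicit-Euler time step (default 0.01).
#' @param t_end End time `T` of the run.
#' @param save_every Record every `save_every`-th step (frame 0 is always
#'   recorded).
#' @param seed Integer seed; a run is fully reproducible from it.
#' @param r0 Initial (and, with shape dynamics off, fixed) aspect ratio;
#'   defaults to `rbar`.
#' @param shape_on Toggle for aspect-ratio dynamics; defaults to
#'   `gamma > 0`.
#' @param junctions_on Toggle for the junction/actin module; defaults to
#'   `kappa > 0 || mu > 0`.
#' @param noise_sd Rotational noise intensity (standard deviation of the
#'   orientation increment per unit time); 0 (the default) disables noise.
#'   Provided as an extension point only.
#' @param allow_shape_and_junctions The junction module assumes a fixed
#'   aspect ratio, so combining it with shape dynamics is refused unless
#'   this experimental flag is set.
#'
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params(nu = 0.2, n_cells = 25, box_l = 10, t_end = 5)
#' p$nu
#' @export
model_params <- function(nu = 0.5, gamma = 0, rbar = 2, kappa = 0, mu = 0,
                         lam = 0, n_cells = 125, box_l = 20, dt = 0.01,
                         t_end = 400, save_every = 100, seed = 1L, r0 = NULL,
                         shape_on = NULL, junctions_on = NULL, noise_sd = 0,
                         allow_shape_and_junctions = FALSE) {
  if (is.null(r0)) r0 <- rbar
  if (is.null(shape_on)) shape_on <- gamma > 0
  if (is.null(junctions_on)) junctions_on <- kappa > 0 || mu > 0
  p <- list(
    nu = nu, gamma = gamma, rbar = rbar, kappa = kappa, mu = mu, lam = lam,
    n_cells = as.integer(n_cells), box_l = box_l, dt = dt, t_end = t_end,
    save_every = as.integer(save_every), seed = as.integer(seed), r0 = r0,
    shape_on = isTRUE(shape_on), junctions_on = isTRUE(junctions_on),
    noise_sd = noise_sd,
    allow_shape_and_junctions = isTRUE(allow_shape_and_junctions)
  )
  class(p) <- "model_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(
    p$nu >= 0, p$gamma >= 0, p$kappa >= 0, p$mu >= 0, p$lam >= 0,
    p$rbar > 1, p$r0 >= 1, p$dt > 0, p$t_end > 0, p$box_l > 0,
    p$n_cells >= 1, p$save_every >= 1, p$noise_sd >= 0
  )
  if (p$shape_on && p$junctions_on && !p$allow_shape_and_junctions) {
    stop("the junction module assumes a fixed aspect ratio; set ",
         "`allow_shape_and_junctions = TRUE` to combine it with shape dynamics",
         call. = FALSE)
  }
  # minimum-image validity: two bounding diameters plus the junction reach
  r_ref <- max(p$r0, if (p$shape_on) p$rbar else p$r0)
  if (p$box_l <= 2 * (2 * sqrt(r_ref)) + p$lam) {
    warning("box_l is small relative to the cell size and junction range; ",
            "minimum-image pair geometry may be ambiguous", call. = FALSE)
  }
  if (p$n_cells * pi > 1.2 * p$box_l^2) {
    warning("total cell area exceeds 1.2 * box area; the population is ",
            "strongly overlapped", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  nu=%g gamma=%g rbar=%g kappa=%g mu=%g lambda=%g\n",
              x$nu, x$gamma, x$rbar, x$kappa, x$mu, x$lam))
  cat(sprintf("  N=%d L=%g dt=%g T=%g save_every=%d seed=%d r0=%g\n",
              x$n_cells, x$box_l, x$dt, x$t_end, x$save_every, x$seed, x$r0))
  cat(sprintf("  shape_on=%s junctions_on=%s noise_sd=%g\n",
              x$shape_on, x$junctions_on, x$noise_sd))
  invisible(x)
}

#' Update a parameter set
#'
#' Returns a copy of `params` with the named fields replaced and the
#' result re-validated. Toggles are re-derived from the new values unless
#' given explicitly.
#'
#' @param params A [model_params()] object.
#' @param ... Named fields to replace.
#' @return A `model_params` object.
#' @export
update_params <- function(params, ...) {
  new <- list(...)
  bad <- setdiff(names(new), names(params))
  if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
  for (nm in names(new)) params[[nm]] <- new[[nm]]
  if (!"shape_on" %in% names(new)) params$shape_on <- params$gamma > 0
  if (!"junctions_on" %in% names(new)) {
    params$junctions_on <- params$kappa > 0 || params$mu > 0
  }
  if ("n_cells" %in% names(new)) params$n_cells <- as.integer(params$n_cells)
  if ("seed" %in% names(new)) params$seed <- as.integer(params$seed)
  if ("save_every" %in% names(new)) params$save_every <- as.integer(params$save_every)
  validate_params(params)
  params
}

#' Published experiment presets
#'
#' Ready-made parameter sets for the model's reference experiments, at two
#' scales. The `"paper"` scale is the full reference setting (N = 125 cells
#' in an L = 20 box); the `"reduced"` scale keeps the same area density
#' (`N * pi / L^2` of about 0.99: N = 50, L = 12.6) and halves the horizon
#' to T = 200, which runs on a desktop in seconds-to-minutes while
#' preserving the non-dimensional physics.
#'
#' @param experiment One of `"base"` (self-propulsion + overlap avoidance,
#'   nu = 0.2, T = 800 at paper scale), `"shape"` (deformable cells,
#'   gamma = 0.1, nu = 0.5, T = 400) or `"junction"` (junctions + actin,
#'   nu = 0.5, kappa = 1, lam = 0.2, mu = 5, T = 400).
#' @param scale `"paper"` or `"reduced"`.
#' @param seed Base seed.
#' @return A [model_params()] object.
#' @examples
#' preset_params("junction", scale = "reduced")
#' @export
preset_params <- function(experiment = c("base", "shape", "junction"),
                          scale = c("reduced", "paper"), seed = 1L) {
  experiment <- match.arg(experiment)
  scale <- match.arg(scale)
  p <- switch(experiment,
    base = model_params(nu = 0.2, t_end = 800, seed = seed),
    shape = model_params(nu = 0.5, gamma = 0.1, t_end = 400, seed = seed),
    junction = model_params(nu = 0.5, kappa = 1, lam = 0.2, mu = 5,
                            t_end = 400, seed = seed)
  )
  if (scale == "reduced") p <- reduced_scale(p)
  p
}

#' Rescale a parameter set to the reduced desk-scale preset
#'
#' Sets N = 50 and L = 12.6 (preserving the reference area density
#' `N * pi / L^2` of about 0.99) and T = 200. All model constants are kept.
#'
#' @param params A [model_params()] object.
#' @return A `model_params` object.
#' @export
reduced_scale <- function(params) {
  update_params(params, n_cells = 50L, box_l = 12.6, t_end = 200,
                shape_on = params$shape_on, junctions_on = params$junctions_on)
}
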