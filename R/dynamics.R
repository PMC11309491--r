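#' Overlap-avoidance translation term for one cell
#'
#' Sums the contact-point force over all of a cell's overlap contacts:
#' `-sum_j sum_k (Y[2k-1] - Y[2k])^perp`, where `perp` is the left-turn
#' map `(x, y) -> (-y, x)` and the `Y` are the ordered, paired boundary
#' intersection points on the cell's own boundary. This equals the
#' negative gradient of the total pairwise overlap area with respect to
#' the cell's centre.
#'
#' @param contacts A single [ellipse_intersect()] result or a list of
#'   them, all belonging to the same cell `i`. Degenerate (containment)
#'   contacts are skipped; the engine handles those by a fallback.
#' @return A length-2 numeric vector `c(dx, dy)`.
#' @export
overlap_translation_term <- function(contacts) {
  contacts <- as_contact_list(contacts)
  out <- c(0, 0)
  for (ct in contacts) {
    if (ct$degenerate_flag == "containment") next
    p <- ct$points
    for (k in seq_len(ct$K)) {
      v <- c(p$px[2 * k - 1] - p$px[2 * k], p$py[2 * k - 1] - p$py[2 * k])
      out <- out - c(-v[2], v[1])
    }
  }
  out
}

#' Overlap-avoidance rotation term for one cell
#'
#' `(2 r / (r^2 + 1)) * sum_k (|X - Y[2k]|^2 - |X - Y[2k-1]|^2)` summed
#' over contacts: the cell turns from the shorter towards the longer of
#' the two segments joining its centre to the paired intersection
#' points, which decreases the overlap area.
#'
#' @inheritParams overlap_translation_term
#' @param centre The cell's centre `c(x, y)` (in the same periodic image
#'   frame as the contact points).
#' @param r The cell's aspect ratio.
#' @return A scalar angular velocity.
#' @export
overlap_rotation_term <- function(contacts, centre, r) {
  contacts <- as_contact_list(contacts)
  tot <- 0
  for (ct in contacts) {
    if (ct$degenerate_flag == "containment") next
    p <- ct$points
    for (k in seq_len(ct$K)) {
      d2 <- (p$px[2 * k] - centre[1])^2 + (p$py[2 * k] - centre[2])^2
      d1 <- (p$px[2 * k - 1] - centre[1])^2 + (p$py[2 * k - 1] - centre[2])^2
      tot <- tot + (d2 - d1)
    }
  }
  2 * r / (r^2 + 1) * tot
}

as_contact_list <- function(contacts) {
  if (is.null(contacts)) return(list())
  if (inherits(contacts, "overlap_contact")) return(list(contacts))
  contacts[!vapply(contacts, is.null, logical(1))]
}

#' Aspect-ratio rate of change for one cell
#'
#' The overlap-driven deformation plus relaxation towards the preferred
#' aspect ratio `rbar`, at fixed cell area:
#' `(4 r^2/(r^2+1)) * sum_k (sin(2*theta[2k-1]) - sin(2*theta[2k])) +
#'  16 gamma (1 + rbar r^3)/(1 + r^2) (1 - r/rbar)`.
#' The `theta` are the boundary coordinates of the cell's ordered contact
#' points; contacts near the cell tips (`theta` near 0 or `pi`) lengthen
#' the cell while contacts on its flanks shorten it.
#'
#' @param thetas Ordered contact-point `theta` values (concatenated
#'   pairs, as in `ellipse_intersect()$points$theta`); may be empty.
#' @param r Aspect ratio (> 0).
#' @param gamma Shape-restoring strength.
#' @param rbar Preferred aspect ratio.
#' @return Scalar `dr/dt`.
#' @examples
#' shape_rate(numeric(0), r = 1, gamma = 0.1, rbar = 2) # relaxes upward
#' @export
shape_rate <- function(thetas, r, gamma, rbar = 2) {
  stopifnot(r > 0, length(thetas) %% 2 == 0)
  overlap <- 0
  if (length(thetas)) {
    odd <- thetas[seq(1, length(thetas), by = 2)]
    even <- thetas[seq(2, length(thetas), by = 2)]
    overlap <- 4 * r^2 / (r^2 + 1) * sum(sin(2 * odd) - sin(2 * even))
  }
  overlap + 16 * gamma * (1 + rbar * r^3) / (1 + r^2) * (1 - r / rbar)
}

#' Right-hand side of the base model for a whole population
#'
#' Assembles, for every cell, the overlap-avoidance translation and
#' rotation terms plus self-propulsion `nu * e(alpha)`:
#' the non-dimensional equations of motion of the base model. Aspect
#' ratios are static here (`dr = 0`); see [shape_rate()] for the shape
#' module and [find_junctions()] for the junction module.
#'
#' @param cells A [cell_population()] tibble.
#' @param params A [model_params()] object (uses `nu` and `box_l`).
#' @return A tibble with columns `cell`, `dx`, `dy`, `dalpha`, `dr`, with
#'   an attribute `events` counting containment fallbacks and degeneracy
#'   jitters.
#' @export
base_rhs <- function(cells, params) {
  d <- cpp_derivs(cells$x, cells$y, cells$alpha, cells$r,
                  params$nu, 0, params$rbar, 0, 0, 0, params$box_l,
                  FALSE, FALSE)
  out <- tibble::tibble(cell = cells$cell, dx = d$dx, dy = d$dy,
                        dalpha = d$dalpha, dr = d$dr)
  attr(out, "events") <- d$events
  out
}

#' Full-model derivatives for a whole population
#'
#' Like [base_rhs()] but with every active module: shape dynamics when
#' `params$shape_on`, junction springs and actin torques when
#' `params$junctions_on`. This is the exact right-hand side the engine
#' integrates.
#'
#' @inheritParams base_rhs
#' @return A tibble like [base_rhs()]'s.
#' @export
model_rhs <- function(cells, params) {
  d <- cpp_derivs(cells$x, cells$y, cells$alpha, cells$r,
                  params$nu, params$gamma, params$rbar, params$kappa,
                  params$mu, params$lam, params$box_l,
                  params$shape_on, params$junctions_on)
  out <- tibble::tibble(cell = cells$cell, dx = d$dx, dy = d$dy,
                        dalpha = d$dalpha, dr = d$dr)
  attr(out, "events") <- d$events
  out
}
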