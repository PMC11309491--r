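#' Front and back endpoints of each cell
#'
#' The junction attachment points `X +/- a * e(alpha)`: the tips of the
#' major axis, with the front in the direction of self-propulsion.
#'
#' @param cells A [cell_population()] tibble.
#' @return A tibble with columns `cell`, `front_x`, `front_y`, `back_x`,
#'   `back_y`.
#' @examples
#' cell_endpoints(cell_population(0, 0, 0, r = 2))
#' @export
cell_endpoints <- function(cells) {
  a <- sqrt(cells$r)
  ex <- a * cos(cells$alpha)
  ey <- a * sin(cells$alpha)
  tibble::tibble(
    cell = cells$cell,
    front_x = cells$x + ex, front_y = cells$y + ey,
    back_x = cells$x - ex, back_y = cells$y - ey
  )
}

#' Active cell-cell junctions of a population state
#'
#' Junctions are deterministic zero-rest-length springs between cell
#' endpoints: one exists for every front/back endpoint pair (any
#' polarity combination, self-pairs excluded) whose minimum-image
#' distance is strictly below the range `lambda`; it breaks as soon as
#' it is stretched beyond that range. The active set is stateless: it is
#' a pure function of the current population state. A cell pair may hold
#' several junctions of different endpoint combinations at once, and an
#' endpoint may be shared by many junctions (clumps).
#'
#' @param cells A [cell_population()] tibble.
#' @param lambda Junction range (non-dimensional length, `>= 0`).
#' @param box_l Periodic box side.
#' @return A tibble with one row per junction (`i < j`): `i`, `end_i`,
#'   `j`, `end_j` (`"front"`/`"back"`), `type` (`"fb"` if the polarities
#'   differ, else `"ffbb"`), `sep_x`, `sep_y` (minimum-image separation
#'   from `i`'s endpoint to `j`'s endpoint) and `dist`.
#' @export
find_junctions <- function(cells, lambda, box_l = Inf) {
  stopifnot(lambda >= 0)
  m <- cpp_find_junctions(cells$x, cells$y, cells$alpha, cells$r,
                          lambda, box_l)
  col <- function(nm) unname(m[, nm])
  tibble::tibble(
    i = as.integer(col("i")),
    end_i = ifelse(col("end_i") > 0, "front", "back"),
    j = as.integer(col("j")),
    end_j = ifelse(col("end_j") > 0, "front", "back"),
    type = ifelse(col("type") == 1, "fb", "ffbb"),
    sep_x = col("sep_x"), sep_y = col("sep_y"), dist = col("dist")
  )
}

junctions_of <- function(junctions, cell) {
  # junction rows seen from `cell`: separation points toward the partner
  mine_i <- dplyr::filter(junctions, .data$i == cell)
  mine_j <- dplyr::filter(junctions, .data$j == cell)
  dplyr::bind_rows(
    dplyr::transmute(mine_i, partner = .data$j, end = .data$end_i,
                     type = .data$type, sep_x = .data$sep_x,
                     sep_y = .data$sep_y),
    dplyr::transmute(mine_j, partner = .data$i, end = .data$end_j,
                     type = .data$type, sep_x = -.data$sep_x,
                     sep_y = -.data$sep_y)
  )
}

#' Junction spring force on one cell
#'
#' Zero-rest-length Hookean pull towards each junction partner's
#' endpoint: `kappa * sum(separations)`.
#'
#' @param junctions A [find_junctions()] tibble.
#' @param cell Index of the cell the term is evaluated for.
#' @param kappa Junction spring strength.
#' @return A length-2 numeric vector.
#' @export
junction_translation_term <- function(junctions, cell, kappa) {
  jn <- junctions_of(junctions, cell)
  kappa * c(sum(jn$sep_x), sum(jn$sep_y))
}

#' Junction spring torque on one cell
#'
#' `(4 kappa r^(3/2) / (r^2 + 1)) * sum(sep . (s * e_perp(alpha)))` with
#' `s = +1` when the cell's junction endpoint is its front and `-1` when
#' it is its back: off-axis pulls at an endpoint rotate the cell.
#'
#' @inheritParams junction_translation_term
#' @param r The cell's aspect ratio.
#' @param alpha The cell's orientation.
#' @return A scalar angular velocity.
#' @export
junction_rotation_term <- function(junctions, cell, r, alpha, kappa) {
  jn <- junctions_of(junctions, cell)
  if (!nrow(jn)) return(0)
  s <- ifelse(jn$end == "front", 1, -1)
  eperp <- c(-sin(alpha), cos(alpha))
  4 * kappa * r^1.5 / (r^2 + 1) *
    sum(s * (jn$sep_x * eperp[1] + jn$sep_y * eperp[2]))
}

#' Actin bending torque on one cell
#'
#' The torque transmitted by supracellular actin bundles through active
#' junctions: `(mu r / (r^2 + 1)) * (-sum_fb sin(alpha_i - alpha_j) +
#' sum_ffbb sin(alpha_i - alpha_j))`. Front-to-back junctions drive
#' polar alignment of the two orientations; front-front and back-back
#' junctions drive anti-polar (head-to-head) alignment — both are the
#' nematic equilibria of the discretised bundle bending energy.
#'
#' @inheritParams junction_rotation_term
#' @param alphas Orientations of all cells, indexed by cell id.
#' @param mu Actin bending strength.
#' @return A scalar angular velocity.
#' @export
actin_rotation_term <- function(junctions, cell, alphas, r, mu) {
  jn <- junctions_of(junctions, cell)
  if (!nrow(jn)) return(0)
  sgn <- ifelse(jn$type == "fb", -1, 1)
  mu * r / (r^2 + 1) * sum(sgn * sin(alphas[cell] - alphas[jn$partner]))
}

#' Junction range as a percentage of the cell length
#'
#' Converts the non-dimensional junction range `lam` into a percentage of
#' one cell length `2a = 2*sqrt(r)`: `100 * lam / (2 * sqrt(r))`. At the
#' reference aspect ratio `r = 2`, `lam = 0.2` is about 7% of a cell
#' length and `lam = 0.8` about 28%.
#'
#' @param lam Junction range(s).
#' @param r Aspect ratio (default 2).
#' @return Percentage(s) of one cell length.
#' @examples
#' junction_range_pct(c(0.2, 0.8))
#' @export
junction_range_pct <- function(lam, r = 2) {
  100 * lam / (2 * sqrt(r))
}

#' Bending energy of a supracellular actin bundle
#'
#' The bundle spanning a junctioned cell pair is discretised with three
#' points (the two far endpoints plus the junction midpoint) at step
#' `q = 2a`, which collapses its bending energy to
#' `m/(4a) * |e(alpha_i) -/+ e(alpha_j)|^2` (minus for front-to-back
#' junctions, plus for front-front/back-back). Used as the test oracle
#' for [actin_rotation_term()], which is its negative gradient times the
#' rotational mobility.
#'
#' @param alpha_i,alpha_j Orientations of the two cells.
#' @param a Semi-major axis.
#' @param m Bending strength.
#' @param type `"fb"` or `"ffbb"`.
#' @return Scalar energy.
#' @examples
#' bending_energy(0, pi / 2, a = sqrt(2), m = 1, type = "fb")
#' @export
bending_energy <- function(alpha_i, alpha_j, a, m, type = c("fb", "ffbb")) {
  type <- match.arg(type)
  stopifnot(a > 0, m >= 0)
  sgn <- if (type == "fb") -1 else 1
  dx <- cos(alpha_i) + sgn * cos(alpha_j)
  dy <- sin(alpha_i) + sgn * sin(alpha_j)
  m / (4 * a) * (dx^2 + dy^2)
}
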