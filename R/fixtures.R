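#' Deterministic two-cell test scenarios
#'
#' Small analytic configurations used throughout the unit tests and
#' examples:
#'
#' * `"overlapping_circles"`: unit circles (`r = 1`) centred at (0, 0)
#'   and (1, 0) — one contact-point pair at `(0.5, +/- sqrt(3)/2)`.
#' * `"symmetric_ellipses"`: congruent `r = 2` ellipses sharing a centre
#'   with orientations 0 and `pi/2` — the four-point contact
#'   configuration.
#' * `"fb_junction_pair"`: collinear `r = 2` cells whose facing front and
#'   back endpoints are 0.1 apart.
#' * `"ff_junction_pair"`: as above but the second cell is turned by
#'   `pi`, so the two fronts face each other.
#' * `"containment"`: one ellipse strictly inside a larger one. A
#'   contained ellipse must have smaller area, so this scenario breaks
#'   the unit-area convention on purpose: the returned table carries
#'   explicit `a` and `b` columns, honoured by the geometry layer only.
#'   It exercises the containment branch of [ellipse_intersect()], which
#'   for equal-area cells can only be reached through numerical
#'   degeneracy.
#'
#' @param name Scenario id.
#' @return A [cell_population()] tibble (two rows; the containment
#'   scenario has extra `a`, `b` columns).
#' @examples
#' two_cell_fixture("overlapping_circles")
#' @export
two_cell_fixture <- function(name = c("overlapping_circles",
                                      "symmetric_ellipses",
                                      "fb_junction_pair",
                                      "ff_junction_pair",
                                      "containment")) {
  name <- match.arg(name)
  a2 <- sqrt(2)
  switch(name,
    overlapping_circles = cell_population(
      x = c(0, 1), y = c(0, 0), alpha = c(0, 0), r = 1
    ),
    symmetric_ellipses = cell_population(
      x = c(0, 0), y = c(0, 0), alpha = c(0, pi / 2), r = 2
    ),
    fb_junction_pair = cell_population(
      x = c(0, 2 * a2 + 0.1), y = c(0, 0), alpha = c(0, 0), r = 2
    ),
    ff_junction_pair = cell_population(
      x = c(0, 2 * a2 + 0.1), y = c(0, 0), alpha = c(0, pi), r = 2
    ),
    containment = {
      cells <- cell_population(x = c(0, 0.3), y = c(0, 0.1),
                               alpha = c(0, pi / 4), r = 1)
      cells$a <- c(2.5, 0.6)
      cells$b <- c(2.0, 0.4)
      cells
    }
  )
}
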