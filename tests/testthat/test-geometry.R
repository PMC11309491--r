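test_that("boundary_point maps boundary coordinates to the ellipse", {
  circ <- cell_population(0, 0, 0, r = 1)
  expect_equal(unlist(boundary_point(circ, theta = 0)[, c("px", "py")]),
               c(px = 1, py = 0))
  # rotated r = 2 ellipse: theta = 0 lands on the tip of the rotated major axis
  rot <- cell_population(0, 0, pi / 2, r = 2)
  expect_equal(unlist(boundary_point(rot, theta = 0)[, c("px", "py")]),
               c(px = 0, py = sqrt(2)), tolerance = 1e-12)
  # s = 0 collapses to the centre for any ellipse
  any_e <- cell_population(1.3, -0.4, 0.7, r = 3)
  expect_equal(unlist(boundary_point(any_e, theta = 2.1, s = 0)[, c("px", "py")]),
               c(px = 1.3, py = -0.4))
  # vectorised over theta
  th <- seq(0, 2 * pi, length.out = 7)
  bp <- boundary_point(circ, theta = th)
  expect_equal(bp$px^2 + bp$py^2, rep(1, 7), tolerance = 1e-12)
})

test_that("axes_from_r preserves unit area", {
  ax <- axes_from_r(c(1, 2, 4))
  expect_equal(ax$a, c(1, sqrt(2), 2))
  expect_equal(ax$b, c(1, 1 / sqrt(2), 0.5))
  expect_equal(ax$a * ax$b, rep(1, 3))
})

test_that("min_image maps displacements into (-L/2, L/2]", {
  expect_equal(min_image(c(19.5, 0), 20), c(-0.5, 0))
  expect_equal(min_image(c(0.3, -0.2), 20), c(0.3, -0.2))
  expect_equal(min_image(c(10, 10), 20), c(10, 10)) # boundary convention
  expect_equal(min_image(-10, 20), 10)
  expect_equal(min_image(c(0.3, -0.2), Inf), c(0.3, -0.2))
})

test_that("circle pair intersection matches the closed form, ordered and paired", {
  cells <- two_cell_fixture("overlapping_circles")
  ct <- ellipse_intersect(cells, 1, 2)
  expect_s3_class(ct, "overlap_contact")
  expect_equal(ct$K, 1)
  # Y1 then Y2 so that the anticlockwise arc Y1 -> Y2 of cell 1 is inside cell 2
  expect_equal(ct$points$px, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(ct$points$py, c(-sqrt(3) / 2, sqrt(3) / 2), tolerance = 1e-9)
  # same point set from cell 2's perspective
  ct2 <- ellipse_intersect(cells, 2, 1)
  expect_equal(sort(ct2$points$py), sort(ct$points$py), tolerance = 1e-9)
})

test_that("orthogonal congruent ellipses give the 4-point contact", {
  cells <- two_cell_fixture("symmetric_ellipses")
  ct <- ellipse_intersect(cells, 1, 2)
  expect_equal(ct$K, 2)
  expect_equal(nrow(ct$points), 4)
  v <- sqrt(2 / 5)
  expect_equal(sort(abs(ct$points$px)), rep(v, 4), tolerance = 1e-9)
  expect_equal(sort(abs(ct$points$py)), rep(v, 4), tolerance = 1e-9)
})

test_that("disjoint and periodic-image pairs are handled", {
  far <- cell_population(x = c(0, 5), y = c(0, 0), alpha = c(0, 0), r = 1)
  expect_null(ellipse_intersect(far, 1, 2, box_l = 20))
  # minimum image puts the second circle at (-0.5, 0)
  wrap <- cell_population(x = c(0, 19.5), y = c(0, 0), alpha = c(0, 0), r = 1)
  ct <- ellipse_intersect(wrap, 1, 2, box_l = 20)
  expect_equal(ct$points$px, c(-0.25, -0.25), tolerance = 1e-9)
  expect_equal(sort(ct$points$py), c(-1, 1) * sqrt(1 - 0.0625),
               tolerance = 1e-9)
})

test_that("coincident ellipses raise; containment is flagged", {
  co <- cell_population(x = c(1, 1), y = c(2, 2), alpha = c(0.3, 0.3), r = 2)
  expect_error(ellipse_intersect(co, 1, 2), "coincident")
  inside <- two_cell_fixture("containment")
  ct <- ellipse_intersect(inside, 1, 2)
  expect_equal(ct$degenerate_flag, "containment")
  expect_equal(nrow(ct$points), 0)
  expect_equal(ct$contained, "j")
  # symmetric query flags the same containment with roles swapped
  ct2 <- ellipse_intersect(inside, 2, 1)
  expect_equal(ct2$degenerate_flag, "containment")
  expect_equal(ct2$contained, "i")
})

test_that("intersection points satisfy both implicit equations", {
  set.seed(11)
  qform <- function(cells, k, px, py) {
    a <- sqrt(cells$r[k]); b <- 1 / a
    dx <- px - cells$x[k]; dy <- py - cells$y[k]
    ca <- cos(cells$alpha[k]); sa <- sin(cells$alpha[k])
    ((ca * dx + sa * dy) / a)^2 + ((-sa * dx + ca * dy) / b)^2 - 1
  }
  counts <- integer(0)
  for (k in 1:200) {
    cells <- cell_population(
      x = c(0, runif(1, -2.5, 2.5)), y = c(0, runif(1, -2.5, 2.5)),
      alpha = runif(2, 0, 2 * pi), r = 1 + runif(2, 0, 3)
    )
    ct <- ellipse_intersect(cells, 1, 2)
    n <- if (is.null(ct)) 0L else nrow(ct$points)
    counts <- c(counts, n)
    if (n > 0) {
      expect_lt(max(abs(qform(cells, 1, ct$points$px, ct$points$py))), 1e-8)
      expect_lt(max(abs(qform(cells, 2, ct$points$px, ct$points$py))), 1e-8)
      # symmetric as a point set
      ct2 <- ellipse_intersect(cells, 2, 1)
      m1 <- ct$points[order(ct$points$px, ct$points$py), c("px", "py")]
      m2 <- ct2$points[order(ct2$points$px, ct2$points$py), c("px", "py")]
      expect_equal(as.matrix(m1), as.matrix(m2), tolerance = 1e-7,
                   ignore_attr = TRUE)
      # paired arcs of cell 1 lie inside cell 2 (sample each arc midpoint)
      for (p in seq_len(ct$K)) {
        t1 <- ct$points$theta[2 * p - 1]; t2 <- ct$points$theta[2 * p]
        if (t2 < t1) t2 <- t2 + 2 * pi
        mid <- boundary_point(cells[1, ], theta = (t1 + t2) / 2)
        expect_lt(qform(cells, 2, mid$px, mid$py), 0)
      }
    }
  }
  expect_true(all(counts %in% c(0L, 2L, 4L)))
  expect_true(any(counts > 0))
})

test_that("rigid rotation of both ellipses rotates the intersection points", {
  set.seed(21)
  for (k in 1:20) {
    pair <- random_overlapping_pair()
    cells <- pair$cells
    phi <- runif(1, 0, 2 * pi)
    Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    xy <- Rm %*% rbind(cells$x, cells$y)
    rot <- cell_population(xy[1, ], xy[2, ], cells$alpha + phi, cells$r)
    ct0 <- pair$contact
    ct1 <- ellipse_intersect(rot, 1, 2)
    p0 <- Rm %*% rbind(ct0$points$px, ct0$points$py)
    expect_equal(sort(round(p0[1, ], 8)), sort(round(ct1$points$px, 8)),
                 tolerance = 1e-7)
    expect_equal(sort(round(p0[2, ], 8)), sort(round(ct1$points$py, 8)),
                 tolerance = 1e-7)
  }
})

test_that("overlap_area matches closed forms", {
  same <- cell_population(x = c(0.5, 0.5), y = c(1, 1), alpha = c(0, 0), r = 1)
  expect_equal(overlap_area(same, 1, 2), pi, tolerance = 1e-6)
  far <- cell_population(x = c(0, 5), y = c(0, 0), alpha = c(0, 0), r = 1)
  expect_equal(overlap_area(far, 1, 2), 0)
  lens <- two_cell_fixture("overlapping_circles")
  expect_equal(overlap_area(lens, 1, 2), 2 * pi / 3 - sqrt(3) / 2,
               tolerance = 1e-6)
  # 100 random circle-circle distances against the closed-form lens area
  set.seed(31)
  d <- runif(100, 0.05, 1.95)
  for (dd in d) {
    cl <- cell_population(x = c(0, dd), y = c(0, 0), alpha = c(0, 0), r = 1)
    expect_equal(overlap_area(cl, 1, 2), circle_lens_area(dd),
                 tolerance = 1e-5)
  }
})
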