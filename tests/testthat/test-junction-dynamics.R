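test_that("cell_endpoints places front and back at the major-axis tips", {
  ep <- cell_endpoints(cell_population(0, 0, 0, r = 2))
  expect_equal(c(ep$front_x, ep$front_y), c(sqrt(2), 0))
  expect_equal(c(ep$back_x, ep$back_y), c(-sqrt(2), 0))
  ep2 <- cell_endpoints(cell_population(1, 1, pi / 2, r = 1))
  expect_equal(c(ep2$front_x, ep2$front_y), c(1, 2), tolerance = 1e-12)
  expect_equal(c(ep2$back_x, ep2$back_y), c(1, 0), tolerance = 1e-12)
  # turning by pi swaps front and back
  ep3 <- cell_endpoints(cell_population(0, 0, pi, r = 2))
  expect_equal(c(ep3$front_x, ep3$back_x), c(-sqrt(2), sqrt(2)),
               tolerance = 1e-12)
})

test_that("find_junctions applies the strict range threshold per endpoint pair", {
  cells <- two_cell_fixture("fb_junction_pair")
  jn <- find_junctions(cells, lambda = 0.2)
  expect_equal(nrow(jn), 1)
  expect_equal(jn$type, "fb")
  expect_equal(jn$end_i, "front")
  expect_equal(jn$end_j, "back")
  expect_equal(jn$dist, 0.1, tolerance = 1e-12)
  expect_equal(nrow(find_junctions(cells, lambda = 0.05)), 0)
  expect_equal(nrow(find_junctions(cells, lambda = 0.1)), 0) # strict <
  # three collinear cells, two fb junctions, middle cell degree 2
  gap <- 2 * sqrt(2) + 0.1
  chain <- cell_population(x = c(0, gap, 2 * gap), y = rep(1, 3),
                           alpha = rep(0, 3), r = 2)
  jn3 <- find_junctions(chain, lambda = 0.2)
  expect_equal(nrow(jn3), 2)
  expect_equal(sort(table(c(jn3$i, jn3$j))[["2"]]), 2)
  # stateless and idempotent
  expect_identical(jn3, find_junctions(chain, lambda = 0.2))
  # ff pairing when the second cell faces the first
  ff <- find_junctions(two_cell_fixture("ff_junction_pair"), lambda = 0.2)
  expect_equal(ff$type, "ffbb")
  expect_equal(c(ff$end_i, ff$end_j), c("front", "front"))
})

test_that("junction spring force and torque follow the endpoint geometry", {
  one <- make_junctions(1, "front", 2, "back", sep_x = 0.1, sep_y = 0)
  expect_equal(junction_translation_term(one, 1, kappa = 1), c(0.1, 0))
  expect_equal(junction_translation_term(one, 2, kappa = 1), c(-0.1, 0))
  none <- make_junctions(integer(0), character(0), integer(0), character(0),
                         numeric(0), numeric(0))
  expect_equal(junction_translation_term(none, 1, kappa = 2), c(0, 0))
  two <- make_junctions(c(1, 1), c("front", "back"), c(2, 3), c("back", "front"),
                        sep_x = c(0.1, -0.1), sep_y = c(0, 0))
  expect_equal(junction_translation_term(two, 1, kappa = 2), c(0, 0))
  # torque: separation parallel to the axis gives none
  expect_equal(junction_rotation_term(one, 1, r = 2, alpha = 0, kappa = 1), 0)
  # off-axis pull at the front: (4 kappa / 2) * 0.1 at r = 1
  perp <- make_junctions(1, "front", 2, "back", sep_x = 0, sep_y = 0.1)
  expect_equal(junction_rotation_term(perp, 1, r = 1, alpha = 0, kappa = 1),
               0.2)
  # the same pull attached at the back flips the sign
  perpb <- make_junctions(1, "back", 2, "front", sep_x = 0, sep_y = 0.1)
  expect_equal(junction_rotation_term(perpb, 1, r = 1, alpha = 0, kappa = 1),
               -0.2)
})

test_that("actin torque aligns fb pairs and anti-aligns ff/bb pairs", {
  fb <- make_junctions(1, "front", 2, "back", 0.05, 0)
  al <- c(0.7, 0.7)
  expect_equal(actin_rotation_term(fb, 1, al, r = 1, mu = 1), 0)
  al2 <- c(pi / 2, 0)
  expect_equal(actin_rotation_term(fb, 1, al2, r = 1, mu = 1), -0.5)
  ff <- make_junctions(1, "front", 2, "front", 0.05, 0)
  expect_equal(actin_rotation_term(ff, 1, c(pi, 0), r = 1, mu = 1), 0,
               tolerance = 1e-12)
})

test_that("bending energy of the discretised supracellular bundle", {
  expect_equal(bending_energy(0.4, 0.4, a = 1, m = 1, type = "fb"), 0)
  expect_equal(bending_energy(0, pi / 2, a = sqrt(2), m = 1, type = "fb"),
               2 / (4 * sqrt(2)))
  expect_equal(bending_energy(0, pi, a = 1, m = 1, type = "ffbb"), 0,
               tolerance = 1e-12)
})

test_that("actin torque is the mobility-scaled bending-energy gradient", {
  set.seed(81)
  h <- 1e-6
  for (k in 1:50) {
    ai <- runif(1, 0, 2 * pi); aj <- runif(1, 0, 2 * pi)
    r <- 1 + runif(1, 0, 3); mu <- runif(1, 0.5, 5)
    type <- sample(c("fb", "ffbb"), 1)
    a <- sqrt(r)
    m <- mu * a / 2 # bundle stiffness matching the non-dimensional mu
    jn <- make_junctions(1, "front", 2, if (type == "fb") "back" else "front",
                         0.01, 0)
    term <- actin_rotation_term(jn, 1, c(ai, aj), r, mu)
    dE <- (bending_energy(ai + h, aj, a, m, type) -
             bending_energy(ai - h, aj, a, m, type)) / (2 * h)
    oracle <- -4 * r / (r^2 + 1) * dE
    expect_equal(term, oracle, tolerance = 1e-6)
  }
})

test_that("a perturbed fb pair converges to aligned, endpoint-joined cells", {
  cells <- two_cell_fixture("fb_junction_pair")
  cells$x <- cells$x + 6
  cells$y <- cells$y + 6
  cells$alpha[1] <- cells$alpha[1] + 0.1
  cells$y[2] <- cells$y[2] + 0.05
  p <- model_params(nu = 0, kappa = 1, mu = 1, lam = 0.3, n_cells = 2,
                    box_l = 20, dt = 0.01, t_end = 50, save_every = 100,
                    r0 = 2, seed = 1)
  tr <- simulate_cells(p, init = cells)
  fin <- get_frame(tr)
  expect_lt(abs(fin$alpha[1] - fin$alpha[2]), 1e-3)
  ep <- cell_endpoints(fin)
  gap <- sqrt((ep$front_x[1] - ep$back_x[2])^2 +
                (ep$front_y[1] - ep$back_y[2])^2)
  expect_lt(gap, 0.02)
})

test_that("kappa = mu = 0 reduces the junction model to the base model exactly", {
  p0 <- model_params(nu = 0.4, n_cells = 20, box_l = 9, dt = 0.01,
                     t_end = 5, save_every = 25, seed = 12)
  p1 <- update_params(p0, lam = 0.2, junctions_on = TRUE)
  tr0 <- simulate_cells(p0)
  tr1 <- simulate_cells(p1)
  expect_identical(tr0$frames, tr1$frames) # bitwise-identical trajectories
  expect_gt(nrow(tr1$junctions), 0) # junctions exist, but exert no force
})
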