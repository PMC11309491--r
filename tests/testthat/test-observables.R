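test_that("nematic alignment is polarity-blind and normalised", {
  even <- cell_population(1:4, 1:4, alpha = rep(0.7, 4), r = 2)
  expect_equal(nematic_alignment(even), 1)
  antipodal <- cell_population(1:4, 1:4, alpha = c(0.7, 0.7 + pi, 0.7,
                                                   0.7 + pi), r = 2)
  expect_equal(nematic_alignment(antipodal), 1)
  crossed <- cell_population(1:4, 1:4, alpha = c(0, 0, pi / 2, pi / 2), r = 2)
  expect_equal(nematic_alignment(crossed), 0, tolerance = 1e-12)
  # invariance under global rotation and partial pi-flips
  set.seed(101)
  cells <- cell_population(runif(40, 0, 20), runif(40, 0, 20),
                           runif(40, 0, 2 * pi), r = 2)
  s0 <- nematic_alignment(cells)
  rot <- cells; rot$alpha <- (rot$alpha + 1.1) %% (2 * pi)
  expect_equal(nematic_alignment(rot), s0, tolerance = 1e-12)
  flip <- cells
  pick <- sample(40, 17)
  flip$alpha[pick] <- (flip$alpha[pick] + pi) %% (2 * pi)
  expect_equal(nematic_alignment(flip), s0, tolerance = 1e-12)
})

test_that("packing fraction is the periodic union area over the box area", {
  one <- cell_population(10, 10, 0.3, r = 2)
  expect_equal(packing_fraction(one, 20), pi / 400, tolerance = 1e-3)
  two <- cell_population(c(5, 15), c(5, 15), c(0, 1), r = 1)
  expect_equal(packing_fraction(two, 20), 2 * pi / 400, tolerance = 1e-3)
  same <- cell_population(c(10, 10), c(10, 10), c(0.3, 0.3), r = 2)
  expect_equal(packing_fraction(same, 20), pi / 400, tolerance = 1e-3)
  # a cell crossing the boundary is wrapped, not clipped
  edge <- cell_population(0.05, 19.9, 1.2, r = 2)
  expect_equal(packing_fraction(edge, 20), pi / 400, tolerance = 1e-3)
  # upper bound N*pi/L^2 with equality iff no overlaps
  set.seed(111)
  grid <- expand.grid(x = seq(2, 18, by = 4), y = seq(2, 18, by = 4))
  spaced <- cell_population(grid$x, grid$y, runif(25, 0, 2 * pi), r = 2)
  expect_equal(packing_fraction(spaced, 20), 25 * pi / 400, tolerance = 1e-3)
  packed <- cell_population(runif(25, 8, 12), runif(25, 8, 12),
                            runif(25, 0, 2 * pi), r = 2)
  expect_lt(packing_fraction(packed, 20), 25 * pi / 400 * 0.9)
})

test_that("contact statistics count partners and maximal interaction runs", {
  p <- model_params(n_cells = 2, box_l = 20, dt = 0.01, t_end = 10,
                    save_every = 10, seed = 1)
  apart <- cell_population(c(2, 12), c(2, 12), c(0, 0), r = 1)
  together <- cell_population(c(2, 3), c(2, 2), c(0, 0), r = 1)
  times <- seq(0, 10, by = 0.1)
  # overlap during exactly the first 50 samples (t in [0, 4.9])
  frames1 <- lapply(times, function(tt) if (tt < 4.95) together else apart)
  tr1 <- make_traj(frames1, times, p)
  cs1 <- contact_stats(tr1)
  expect_equal(cs1$partners$n_partners, c(1, 1))
  expect_equal(nrow(cs1$durations), 1)
  expect_equal(cs1$durations$duration, 5.0)
  # two maximal runs: samples 1-10 and 20-30 (durations 1.0 and 1.1)
  on <- c(rep(TRUE, 10), rep(FALSE, 9), rep(TRUE, 11),
          rep(FALSE, length(times) - 30))
  frames2 <- lapply(seq_along(times), function(k) {
    if (on[k]) together else apart
  })
  cs2 <- contact_stats(make_traj(frames2, times, p))
  expect_equal(sort(cs2$durations$duration), c(1.0, 1.1))
  # isolated throughout
  cs3 <- contact_stats(make_traj(lapply(times, function(tt) apart), times, p))
  expect_equal(cs3$partners$n_partners, c(0, 0))
  expect_true(is.na(cs3$mean_duration))
  # window outside the trajectory errors
  expect_error(contact_stats(tr1, window_start = 5), "not covered")
})

test_that("alignment length scale separates ordered, noisy and domain states", {
  set.seed(121)
  n <- 500
  xs <- runif(n, 0, 20); ys <- runif(n, 0, 20)
  ordered <- cell_population(xs, ys, alpha = rep(1, n), r = 2)
  expect_equal(alignment_length_scale(ordered, 20), 20)
  noisy <- cell_population(xs, ys, alpha = runif(n, 0, 2 * pi), r = 2)
  expect_lt(alignment_length_scale(noisy, 20), 1)
  halves <- cell_population(xs, ys,
                            alpha = ifelse(xs < 10, 0, pi / 2), r = 2)
  ell <- alignment_length_scale(halves, 20)
  expect_gt(ell, 0.5)
  expect_lt(ell, 20)
})

test_that("junction graphs collapse parallel junctions and report degrees", {
  cells <- cell_population(1:3, rep(1, 3), rep(0, 3), r = 2)
  empty <- make_junctions(integer(0), character(0), integer(0), character(0),
                          numeric(0), numeric(0))
  jg0 <- junction_graph(cells, empty)
  expect_equal(degree_fraction(jg0, 0), 1)
  expect_equal(jg0$n_components, 3)
  chain <- make_junctions(c(1, 2), c("front", "front"), c(2, 3),
                          c("back", "back"), c(0.1, 0.1), c(0, 0))
  jg1 <- junction_graph(cells, chain)
  expect_equal(jg1$degrees$degree, c(1, 2, 1))
  expect_equal(degree_fraction(jg1, 2), 1 / 3)
  expect_equal(jg1$n_components, 1)
  # an fb and an ff junction between the same pair form a single edge
  multi <- make_junctions(c(1, 1), c("front", "front"), c(2, 2),
                          c("back", "front"), c(0.1, 0.1), c(0, 0))
  jg2 <- junction_graph(cells[1:2, ], multi)
  expect_equal(igraph::ecount(jg2$graph), 1)
  expect_equal(jg2$degrees$degree, c(1, 1))
  expect_equal(sum(jg2$degree_fractions$fraction), 1)
})

test_that("degree-alignment correlation recovers constructed relationships", {
  set.seed(131)
  pct0 <- runif(20, 10, 60)
  df <- tibble::tibble(
    alignment = 1 - pct0 / 100,
    pct_degree_0 = pct0,
    pct_degree_1 = rep(25, 20), # constant: correlation undefined
    pct_degree_2 = 100 - pct0 - 25
  )
  out <- degree_alignment_correlation(df)
  expect_equal(out$r[out$degree == 0], -1)
  expect_true(is.na(out$r[out$degree == 1]))
  expect_equal(out$r[out$degree == 2], 1)
  expect_equal(out$slope[out$degree == 0], -0.01)
})

test_that("observables_report gathers the headline measurements", {
  p <- model_params(nu = 0.4, kappa = 1, lam = 0.3, n_cells = 12, box_l = 7,
                    dt = 0.01, t_end = 12, save_every = 10, seed = 6)
  rep <- observables_report(simulate_cells(p), ngrid = 512)
  expect_equal(nrow(rep), 1)
  expect_true(rep$alignment >= 0 && rep$alignment <= 1)
  expect_true(rep$packing_fraction > 0 && rep$packing_fraction <= 1)
  expect_true(is.finite(rep$mean_partners))
  expect_true(rep$mean_partners >= 0 && rep$mean_partners <= 11)
  expect_lte(rep$pct_degree_0 + rep$pct_degree_1 + rep$pct_degree_2, 100 + 1e-9)
})
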