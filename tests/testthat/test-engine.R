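test_that("initialisation is uniform in the box and seed-reproducible", {
  p <- model_params(n_cells = 125, box_l = 20, seed = 42)
  a <- init_population(p)
  b <- init_population(p)
  expect_identical(a, b)
  expect_equal(nrow(a), 125)
  expect_true(all(a$x >= 0 & a$x < 20 & a$y >= 0 & a$y < 20))
  expect_true(all(a$alpha >= 0 & a$alpha < 2 * pi))
  expect_equal(unique(a$r), p$rbar)
  d <- init_population(update_params(p, seed = 43))
  expect_false(isTRUE(all.equal(a$x, d$x)))
  # the caller's RNG stream is untouched
  set.seed(1); u1 <- runif(1)
  set.seed(1); invisible(init_population(p)); u2 <- runif(1)
  expect_identical(u1, u2)
})

test_that("neighbor_candidates is a bounding-circle superset of true overlaps", {
  two <- cell_population(x = c(0, 10), y = c(0, 0), alpha = c(0, 0), r = 2)
  expect_equal(nrow(neighbor_candidates(two, 20)), 0)
  near <- cell_population(x = c(0, 2.5), y = c(0, 0), alpha = c(0, 0), r = 2)
  expect_equal(nrow(neighbor_candidates(near, 20)), 1)
  set.seed(91)
  for (k in 1:30) {
    n <- 20
    cells <- cell_population(runif(n, 0, 9), runif(n, 0, 9),
                             runif(n, 0, 2 * pi), r = 1 + runif(n, 0, 2))
    cand <- neighbor_candidates(cells, 9)
    truth <- overlapping_pairs(cells, 9)
    key <- function(d) paste(d$i, d$j)
    expect_true(all(key(truth) %in% key(cand)))
    # and the narrow phase agrees with an exhaustive intersection check
    all_pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    slow <- vapply(seq_len(nrow(all_pairs)), function(m) {
      !is.null(ellipse_intersect(cells, all_pairs[m, 2], all_pairs[m, 1],
                                 box_l = 9))
    }, logical(1))
    expect_setequal(key(truth),
                    paste(pmin(all_pairs[slow, 2], all_pairs[slow, 1]),
                          pmax(all_pairs[slow, 2], all_pairs[slow, 1])))
  }
})

test_that("sim_step performs one wrapped Euler update", {
  lone <- cell_population(5, 5, 0, r = 2)
  p <- model_params(nu = 0.5, n_cells = 1, box_l = 20, dt = 0.01)
  s1 <- sim_step(lone, p)
  expect_equal(s1$x, 5.005)
  expect_equal(s1$y, 5)
  edge <- cell_population(19.999, 5, 0, r = 2)
  s2 <- sim_step(edge, p)
  expect_equal(s2$x, 0.004, tolerance = 1e-9)
  # no propulsion, no neighbours, no junctions: a fixed point
  s3 <- sim_step(lone, update_params(p, nu = 0))
  expect_equal(s3, lone)
})

test_that("simulate_cells records the documented frame grid deterministically", {
  p <- model_params(nu = 0.2, n_cells = 10, box_l = 8, dt = 0.01, t_end = 1,
                    save_every = 10, seed = 7)
  tr <- simulate_cells(p)
  times <- unique(tr$frames$t)
  expect_equal(times, seq(0, 1, by = 0.1))
  expect_equal(nrow(tr$frames), 11 * 10)
  tr2 <- simulate_cells(p)
  expect_identical(tr$frames, tr2$frames)
  expect_false(identical(
    tr$frames,
    simulate_cells(update_params(p, seed = 8))$frames
  ))
  expect_true(all(is.finite(as.matrix(tr$frames))))
})

test_that("a uniform shift of the initial state shifts the whole trajectory", {
  p <- model_params(nu = 0.3, n_cells = 12, box_l = 9, dt = 0.01, t_end = 2,
                    save_every = 50, seed = 19)
  init <- init_population(p)
  shift <- c(3.7, -2.2)
  shifted <- init
  shifted$x <- (init$x + shift[1]) %% p$box_l
  shifted$y <- (init$y + shift[2]) %% p$box_l
  tr0 <- simulate_cells(p, init = init)
  tr1 <- simulate_cells(p, init = shifted)
  f0 <- get_frame(tr0)
  f1 <- get_frame(tr1)
  expect_lt(max(abs(min_image(f1$x - f0$x - shift[1], p$box_l))), 1e-6)
  expect_lt(max(abs(min_image(f1$y - f0$y - shift[2], p$box_l))), 1e-6)
  expect_lt(max(abs(f1$alpha - f0$alpha)), 1e-6)
})

test_that("optional rotational noise is off by default and seed-stable", {
  p <- model_params(nu = 0.2, n_cells = 8, box_l = 8, dt = 0.01, t_end = 1,
                    save_every = 100, seed = 3)
  pn <- update_params(p, noise_sd = 0.5)
  trn1 <- simulate_cells(pn)
  trn2 <- simulate_cells(pn)
  expect_identical(trn1$frames, trn2$frames)
  expect_false(identical(simulate_cells(p)$frames, trn1$frames))
})

test_that("base-model alignment rises from the isotropic start", {
  finals <- vapply(1:3, function(s) {
    p <- model_params(nu = 0.2, n_cells = 30, box_l = 10, dt = 0.01,
                      t_end = 60, save_every = 200, seed = 100 + s)
    tr <- simulate_cells(p)
    nematic_alignment(get_frame(tr)) - nematic_alignment(get_frame(tr, "first"))
  }, numeric(1))
  expect_gt(mean(finals), 0)
})
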