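# shared helpers: random overlapping pairs, synthetic contacts/junctions,
# finite-difference oracles against the polygon-clipped overlap area

random_overlapping_pair <- function(rmax = 4) {
  repeat {
    cells <- cell_population(
      x = c(0, runif(1, -1.5, 1.5)), y = c(0, runif(1, -1.5, 1.5)),
      alpha = runif(2, 0, 2 * pi), r = 1 + runif(2, 0, rmax - 1)
    )
    ct <- ellipse_intersect(cells, 1, 2)
    if (!is.null(ct) && ct$degenerate_flag == "none") {
      return(list(cells = cells, contact = ct))
    }
  }
}

# central finite differences of the overlap area in one coordinate of cell 1
fd_overlap_gradient <- function(cells, what = c("x", "y", "alpha", "r"),
                                h = 1e-5, n = 2048) {
  what <- match.arg(what)
  bump <- function(d) {
    cl <- cells
    cl[[what]][1] <- cl[[what]][1] + d
    overlap_area(cl, 1, 2, n_vertices = n)
  }
  (bump(h) - bump(-h)) / (2 * h)
}

# synthetic overlap_contact from explicit points (px, py, theta in Y-order)
make_contact <- function(px, py, theta, i = 1L, j = 2L) {
  structure(
    list(i = i, j = j, K = length(px) / 2,
         points = tibble::tibble(px = px, py = py, theta = theta),
         points_j = tibble::tibble(px = px, py = py, theta = theta),
         contained = "none", degenerate_flag = "none"),
    class = "overlap_contact"
  )
}

# synthetic junction table in find_junctions() layout
make_junctions <- function(i, end_i, j, end_j, sep_x, sep_y) {
  tibble::tibble(
    i = as.integer(i), end_i = end_i, j = as.integer(j), end_j = end_j,
    type = ifelse(end_i != end_j, "fb", "ffbb"),
    sep_x = sep_x, sep_y = sep_y, dist = sqrt(sep_x^2 + sep_y^2)
  )
}

# synthetic trajectory from a list of frames (tibbles with cell,x,y,alpha,r)
make_traj <- function(frames_list, times, params) {
  frames <- dplyr::bind_rows(
    purrr::map2(frames_list, times, function(fr, tt) {
      dplyr::mutate(fr, t = tt, .before = 1)
    })
  )
  structure(
    list(frames = frames,
         junctions = tibble::tibble(t = numeric(), i = integer(),
                                    end_i = character(), j = integer(),
                                    end_j = character(), type = character()),
         params = params,
         events = c(containment = 0L, clamp_lo = 0L, clamp_hi = 0L,
                    jitter = 0L),
         seed = params$seed),
    class = "cell_traj"
  )
}

total_overlap_area <- function(cells, box_l, n = 512) {
  pr <- overlapping_pairs(cells, box_l)
  if (!nrow(pr)) return(0)
  sum(purrr::map2_dbl(pr$i, pr$j, function(i, j) {
    overlap_area(cells, i, j, box_l, n_vertices = n)
  }))
}

# closed-form area of the lens of two unit circles at centre distance d
circle_lens_area <- function(d) {
  if (d >= 2) return(0)
  2 * acos(d / 2) - d / 2 * sqrt(4 - d^2)
}
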