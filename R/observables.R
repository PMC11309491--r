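#' Global nematic alignment of a population
#'
#' The modulus of the mean double-angle phasor,
#' `S = sqrt(mean(cos 2a)^2 + mean(sin 2a)^2)`: the standard 2D nematic
#' order parameter. `S = 1` for perfect (polarity-blind) alignment and
#' `S` of order `1/sqrt(N)` for an isotropic population.
#'
#' @param cells A [cell_population()] tibble (any tibble with `alpha`).
#' @return A scalar in `[0, 1]`.
#' @examples
#' nematic_alignment(cell_population(1:4, 1:4, alpha = c(0, pi, 0, pi)))
#' @export
nematic_alignment <- function(cells) {
  a <- cells$alpha
  sqrt(mean(cos(2 * a))^2 + mean(sin(2 * a))^2)
}

#' Alignment over time
#'
#' @param traj A `cell_traj` object.
#' @return A tibble with columns `t` and `alignment`.
#' @export
alignment_series <- function(traj) {
  traj$frames |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(
      alignment = sqrt(mean(cos(2 * .data$alpha))^2 +
                         mean(sin(2 * .data$alpha))^2),
      .groups = "drop"
    )
}

#' Equilibrated alignment of a run
#'
#' The population reaches a dynamic equilibrium in which cells still move
#' but the alignment is statistically stationary; this reports the mean
#' alignment over the final fraction `frac` of recorded frames.
#'
#' @param traj A `cell_traj` object.
#' @param frac Final fraction of frames to average over (default 0.1).
#' @return A scalar in `[0, 1]`.
#' @export
equilibrated_alignment <- function(traj, frac = 0.1) {
  s <- alignment_series(traj)
  k <- max(1L, ceiling(frac * nrow(s)))
  mean(utils::tail(s$alignment, k))
}

#' Packing fraction of a population
#'
#' The fraction of the periodic box covered by the union of all cells,
#' computed on a raster of `ngrid^2` sample points. Since every cell has
#' area `pi`, the packing fraction is at most `N * pi / L^2`, with
#' equality exactly when no two cells overlap — so at fixed `N` and `L`,
#' a higher packing fraction means less mutual overlap.
#'
#' @param cells A [cell_population()] tibble.
#' @param box_l Box side length.
#' @param ngrid Raster resolution per side (default 2048).
#' @return A scalar in `(0, 1]`.
#' @export
packing_fraction <- function(cells, box_l, ngrid = 2048L) {
  stopifnot(ngrid >= 64)
  cpp_packing_fraction(cells$x, cells$y, cells$alpha, cells$r,
                       box_l, as.integer(ngrid))
}

#' Contact statistics over a time window
#'
#' Samples the trajectory at regular intervals across a window and
#' reports, per cell, the number of distinct cells it overlapped with at
#' any sampled time, and, per cell pair, the durations of their maximal
#' runs of consecutive overlapping samples (`run length * interval`;
#' a pair that separates and meets again contributes several
#' interactions).
#'
#' @param traj A `cell_traj` object whose recorded frames cover the
#'   window at the sampling interval.
#' @param window_start Start time of the window (default 0).
#' @param window_length Window duration (default 10).
#' @param sample_interval Sampling interval (default 0.1, i.e. 100 time
#'   points over the default window).
#' @return A list with `partners` (tibble `cell`, `n_partners`),
#'   `durations` (tibble `i`, `j`, `duration`), and scalar summaries
#'   `mean_partners` and `mean_duration`.
#' @export
contact_stats <- function(traj, window_start = 0, window_length = 10,
                          sample_interval = 0.1) {
  times <- unique(traj$frames$t)
  wanted <- window_start + sample_interval * (seq_len(round(
    window_length / sample_interval)) - 1)
  if (min(wanted) < min(times) - 1e-9 || max(wanted) > max(times) + 1e-9) {
    stop("window [", window_start, ", ", window_start + window_length,
         "] is not covered by the trajectory")
  }
  idx <- vapply(wanted, function(w) which.min(abs(times - w)), integer(1))
  if (any(abs(times[idx] - wanted) > sample_interval / 2)) {
    stop("trajectory frames are too sparse for sample_interval = ",
         sample_interval)
  }
  L <- traj$params$box_l
  n <- traj$params$n_cells
  overlaps <- lapply(times[idx], function(tt) {
    overlapping_pairs(get_frame(traj, tt), L)
  })
  key <- function(d) (d$i - 1) * n + d$j
  all_keys <- sort(unique(unlist(lapply(overlaps, key))))
  partners <- rep(0L, n)
  durations <- tibble::tibble(i = integer(), j = integer(),
                              duration = numeric())
  if (length(all_keys)) {
    present <- vapply(overlaps, function(d) all_keys %in% key(d),
                      logical(length(all_keys)))
    present <- matrix(present, nrow = length(all_keys))
    ii <- ((all_keys - 1) %/% n) + 1L
    jj <- ((all_keys - 1) %% n) + 1L
    partners <- tabulate(c(ii, jj), nbins = n)
    runs <- lapply(seq_along(all_keys), function(k) {
      r <- rle(present[k, ])
      len <- r$lengths[r$values]
      if (!length(len)) return(NULL)
      tibble::tibble(i = ii[k], j = jj[k], duration = len * sample_interval)
    })
    durations <- dplyr::bind_rows(runs)
  }
  list(
    partners = tibble::tibble(cell = seq_len(n), n_partners = partners),
    durations = durations,
    mean_partners = mean(partners),
    mean_duration = if (nrow(durations)) mean(durations$duration) else NA_real_
  )
}

#' Alignment length scale of a population
#'
#' Bins the nematic pair correlation
#' `C(d) = <cos 2(alpha_i - alpha_j)>` over minimum-image pair distances
#' (bin width `bin_width`, up to `L/2`) and fits `C(d) = exp(-d/l)` by
#' least squares, returning the correlation length `l` capped at `L`.
#' A population aligned into a single domain saturates the cap; an
#' isotropic one returns a length below the cell size.
#'
#' @param cells A [cell_population()] tibble (N >= 10).
#' @param box_l Box side length.
#' @param bin_width Distance bin width (default 0.5).
#' @return The correlation length (scalar, capped at `box_l`).
#' @export
alignment_length_scale <- function(cells, box_l, bin_width = 0.5) {
  n <- nrow(cells)
  stopifnot(n >= 10)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- min_image(cells$x[pr[, 2]] - cells$x[pr[, 1]], box_l)
  dy <- min_image(cells$y[pr[, 2]] - cells$y[pr[, 1]], box_l)
  d <- sqrt(dx^2 + dy^2)
  cc <- cos(2 * (cells$alpha[pr[, 2]] - cells$alpha[pr[, 1]]))
  keep <- d <= box_l / 2
  bins <- floor(d[keep] / bin_width)
  corr <- tapply(cc[keep], bins, mean)
  dmid <- (as.numeric(names(corr)) + 0.5) * bin_width
  cap <- box_l
  if (all(corr > 0.9)) return(cap)          # single aligned domain
  if (corr[[1]] < 0.05) return(bin_width / 2) # decorrelated at contact range
  pos <- corr > 0.02
  if (sum(pos) < 2) return(bin_width / 2)
  ell0 <- tryCatch({
    f <- lm(log(corr[pos]) ~ 0 + dmid[pos])
    -1 / coef(f)[[1]]
  }, error = function(e) NA_real_)
  ell <- tryCatch({
    st <- if (is.finite(ell0) && ell0 > 0) min(ell0, cap) else 1
    f <- nls(corr ~ exp(-dmid / ell), start = list(ell = st),
             control = list(warnOnly = TRUE))
    coef(f)[["ell"]]
  }, error = function(e) ell0)
  if (!is.finite(ell) || ell <= 0) {
    warning("degenerate correlation-length fit; returning the cap")
    return(cap)
  }
  min(ell, cap)
}

#' Junction graph of a population state
#'
#' Represents cells as nodes and junctioned cell pairs as edges of a
#' simple undirected graph (parallel junctions between the same pair
#' collapse to one edge). The node degree — the number of distinct cells
#' a cell is junctioned to — is the key quantity: degree-2 cells chain
#' into the linear arrangements associated with strong, long-ranged
#' alignment.
#'
#' @param cells A [cell_population()] tibble.
#' @param junctions A [find_junctions()] tibble (or the junction rows of
#'   one recorded frame).
#' @return A list of class `junction_graph` with `graph` (an
#'   \pkg{igraph} object), `degrees` (tibble `cell`, `degree`),
#'   `degree_fractions` (tibble `degree`, `fraction`; fractions sum
#'   to 1) and `n_components`.
#' @export
junction_graph <- function(cells, junctions) {
  n <- nrow(cells)
  edges <- dplyr::distinct(junctions, .data$i, .data$j)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  deg <- igraph::degree(g)
  fractions <- tibble::as_tibble(as.data.frame(table(deg),
                                               stringsAsFactors = FALSE))
  names(fractions) <- c("degree", "n")
  fractions$degree <- as.integer(fractions$degree)
  fractions$fraction <- fractions$n / n
  structure(
    list(
      graph = g,
      degrees = tibble::tibble(cell = seq_len(n), degree = as.integer(deg)),
      degree_fractions = fractions[, c("degree", "fraction")],
      n_components = igraph::components(g)$no
    ),
    class = "junction_graph"
  )
}

#' @export
print.junction_graph <- function(x, ...) {
  cat(sprintf("<junction_graph> %d cells, %d edges, %d components\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$n_components))
  print(x$degree_fractions)
  invisible(x)
}

#' Degree fraction of a junction graph
#'
#' @param jg A [junction_graph()] result.
#' @param degree Node degree of interest.
#' @return The fraction of cells with exactly that degree.
#' @export
degree_fraction <- function(jg, degree) {
  hit <- jg$degree_fractions$degree == degree
  if (any(hit)) jg$degree_fractions$fraction[hit] else 0
}

#' Correlation of junction-graph degree with alignment across an ensemble
#'
#' For each node degree (0, 1, 2 by default), the Pearson correlation and
#' least-squares line between the percentage of cells of that degree and
#' the final alignment, across independent simulation runs.
#'
#' @param ensemble Either a list of `cell_traj` objects (final frames are
#'   used) or a tibble with columns `alignment` and `pct_degree_0`,
#'   `pct_degree_1`, ... (one row per run), as produced by
#'   [ensemble_degree_summary()].
#' @param degrees Degrees to report (default `0:2`).
#' @return A tibble with columns `degree`, `r` (Pearson correlation; `NA`
#'   when the degree percentage has zero variance), `slope`, `intercept`
#'   and `n_runs`.
#' @export
degree_alignment_correlation <- function(ensemble, degrees = 0:2) {
  df <- if (is.data.frame(ensemble)) ensemble else {
    ensemble_degree_summary(ensemble, degrees)
  }
  stopifnot(nrow(df) >= 10)
  purrr::map_dfr(degrees, function(d) {
    colname <- paste0("pct_degree_", d)
    pct <- df[[colname]]
    if (is.null(pct)) stop("missing column ", colname)
    if (sd(pct) < 1e-12 || sd(df$alignment) < 1e-12) {
      return(tibble::tibble(degree = d, r = NA_real_, slope = NA_real_,
                            intercept = NA_real_, n_runs = nrow(df)))
    }
    fit <- lm(df$alignment ~ pct)
    tibble::tibble(
      degree = d, r = cor(pct, df$alignment),
      slope = coef(fit)[[2]], intercept = coef(fit)[[1]], n_runs = nrow(df)
    )
  })
}

#' Per-run degree percentages and alignment for an ensemble
#'
#' @param trajs A list of `cell_traj` objects.
#' @param degrees Degrees to tabulate.
#' @return A tibble with one row per run: `run`, `alignment`, and
#'   `pct_degree_<d>` columns (percent of cells of each degree at the
#'   final frame).
#' @export
ensemble_degree_summary <- function(trajs, degrees = 0:2) {
  purrr::imap_dfr(trajs, function(tr, k) {
    cells <- get_frame(tr)
    jg <- junction_graph(cells, get_junctions(tr))
    row <- tibble::tibble(run = k, alignment = nematic_alignment(cells))
    for (d in degrees) {
      row[[paste0("pct_degree_", d)]] <- 100 * degree_fraction(jg, d)
    }
    row
  })
}

#' Summary report of a run's observables
#'
#' @param traj A `cell_traj` object.
#' @param ngrid Raster resolution for the packing fraction.
#' @return A one-row tibble: equilibrated and final alignment, packing
#'   fraction, mean aspect ratio, alignment length scale, contact
#'   statistics over the final 10 time units (at the recorded frame
#'   cadence; `NA` when frames are too sparse), junction count and
#'   degree fractions (0-2) at the final frame.
#' @export
observables_report <- function(traj, ngrid = 1024L) {
  cells <- get_frame(traj)
  jn <- get_junctions(traj)
  jg <- junction_graph(cells, jn)
  times <- unique(traj$frames$t)
  frame_dt <- if (length(times) > 1) min(diff(times)) else NA_real_
  cs <- tryCatch(
    contact_stats(traj, window_start = max(times) - 10, window_length = 10,
                  sample_interval = frame_dt),
    error = function(e) list(mean_partners = NA_real_,
                             mean_duration = NA_real_)
  )
  tibble::tibble(
    alignment = equilibrated_alignment(traj),
    alignment_final = nematic_alignment(cells),
    packing_fraction = packing_fraction(cells, traj$params$box_l, ngrid),
    mean_r = mean(cells$r),
    length_scale = if (nrow(cells) >= 10) {
      alignment_length_scale(cells, traj$params$box_l)
    } else NA_real_,
    mean_partners = cs$mean_partners,
    mean_duration = cs$mean_duration,
    n_junctions = nrow(jn),
    pct_degree_0 = 100 * degree_fraction(jg, 0),
    pct_degree_1 = 100 * degree_fraction(jg, 1),
    pct_degree_2 = 100 * degree_fraction(jg, 2)
  )
}
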