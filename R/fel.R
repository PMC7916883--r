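# Two-dimensional free-energy landscapes by Boltzmann inversion of the
# sampled density over two reaction coordinates (eigenvector projections),
# and basin enumeration at energy levels.

#' Build a 2-D free-energy landscape from two projection series
#'
#' Bins the joint samples of two reaction coordinates on a regular grid
#' and converts occupancies to relative free energies by Boltzmann
#' inversion, `F_i = -kB T ln(N_i / N_max)`, where `N_i` is the bin count
#' and `N_max` the count of the most populated bin. The most probable bin
#' therefore sits at `F = 0` and every occupied bin has `F >= 0`; empty
#' bins are undefined (`+Inf`). Bin edges span the data range; intervals
#' are right-open except the last, so extreme frames are always counted.
#'
#' @param series1,series2 Equal-length numeric vectors or
#'   [project_trajectory()] tibbles (reaction coordinates, nm).
#' @param nbins Bins per axis (scalar or length-2), `>= 2`.
#' @param temperature Simulation temperature in K.
#' @return A `fel_grid`: list with `counts`, `free_energy` (matrices,
#'   `nbins1 x nbins2`, kJ/mol), `edges1`, `edges2`, `centers1`,
#'   `centers2`, `temperature`, `kB`, `n_frames`, `n_max`.
#' @export
build_fel <- function(series1, series2, nbins = 32, temperature = 300) {
  v1 <- if (is.data.frame(series1)) series1$proj_nm else as.numeric(series1)
  v2 <- if (is.data.frame(series2)) series2$proj_nm else as.numeric(series2)
  if (length(v1) != length(v2)) abort("reaction-coordinate series must have equal length")
  if (length(v1) == 0) abort("cannot build a landscape from zero frames")
  nbins <- rep(as.integer(nbins), length.out = 2)
  if (any(nbins < 2)) abort("need at least 2 bins per axis")
  bin_of <- function(v, edges) {
    b <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
    b
  }
  r1 <- range(v1)
  r2 <- range(v2)
  if (diff(r1) == 0) r1 <- r1 + c(-0.5, 0.5)
  if (diff(r2) == 0) r2 <- r2 + c(-0.5, 0.5)
  e1 <- seq(r1[1], r1[2], length.out = nbins[1] + 1)
  e2 <- seq(r2[1], r2[2], length.out = nbins[2] + 1)
  counts <- matrix(0L, nrow = nbins[1], ncol = nbins[2])
  b1 <- bin_of(v1, e1)
  b2 <- bin_of(v2, e2)
  for (i in seq_along(b1)) counts[b1[i], b2[i]] <- counts[b1[i], b2[i]] + 1L
  n_max <- max(counts)
  fe <- matrix(Inf, nrow = nbins[1], ncol = nbins[2])
  occ <- counts > 0
  fe[occ] <- -.kB * temperature * log(counts[occ] / n_max)
  structure(list(
    counts = counts, free_energy = fe,
    edges1 = e1, edges2 = e2,
    centers1 = (e1[-1] + e1[-length(e1)]) / 2,
    centers2 = (e2[-1] + e2[-length(e2)]) / 2,
    temperature = temperature, kB = .kB,
    n_frames = length(v1), n_max = n_max
  ), class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat(sprintf(
    "<fel_grid> %d x %d bins, %d frames at T = %g K; F range 0..%.2f kJ/mol\n",
    nrow(x$counts), ncol(x$counts), x$n_frames, x$temperature,
    max(x$free_energy[is.finite(x$free_energy)])
  ))
  invisible(x)
}

# flood fill over the bin lattice with 8-neighbour connectivity
.label_components <- function(mask) {
  lab <- matrix(0L, nrow = nrow(mask), ncol = ncol(mask))
  cur <- 0L
  nr <- nrow(mask)
  nc <- ncol(mask)
  for (i0 in seq_len(nr)) {
    for (j0 in seq_len(nc)) {
      if (mask[i0, j0] && lab[i0, j0] == 0L) {
        cur <- cur + 1L
        queue <- matrix(c(i0, j0), ncol = 2)
        lab[i0, j0] <- cur
        while (nrow(queue) > 0) {
          p <- queue[1, ]
          queue <- queue[-1, , drop = FALSE]
          for (di in -1:1) {
            for (dj in -1:1) {
              ii <- p[1] + di
              jj <- p[2] + dj
              if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
                  mask[ii, jj] && lab[ii, jj] == 0L) {
                lab[ii, jj] <- cur
                queue <- rbind(queue, c(ii, jj))
              }
            }
          }
        }
      }
    }
  }
  lab
}

#' Count free-energy basins below an energy level
#'
#' A basin is a connected component (8-neighbour connectivity on the bin
#' lattice) of bins with finite `F < level`. Basin structure is invariant
#' to a constant shift of the energy scale applied together with the
#' level.
#'
#' @param grid A [build_fel()] result.
#' @param level Energy level in kJ/mol.
#' @return A list with `n_basins`, `basins` (tibble `basin`, `min_f`,
#'   `area_bins`) and `labels` (bin lattice matrix of basin ids, 0 =
#'   above level).
#' @export
count_basins <- function(grid, level) {
  stopifnot(inherits(grid, "fel_grid"))
  mask <- is.finite(grid$free_energy) & grid$free_energy < level
  lab <- .label_components(mask)
  k <- max(lab)
  basins <- if (k > 0) {
    bind_rows(lapply(seq_len(k), function(b) {
      sel <- lab == b
      tibble(basin = b, min_f = min(grid$free_energy[sel]), area_bins = sum(sel))
    }))
  } else {
    tibble(basin = integer(0), min_f = numeric(0), area_bins = integer(0))
  }
  list(n_basins = k, basins = basins, labels = lab)
}

#' Basin census over a set of energy levels
#'
#' @param grid A [build_fel()] result.
#' @param levels Energy levels (kJ/mol) at which to count basins.
#' @return A tibble with one row per (level, basin): `level`, `n_basins`,
#'   `basin`, `min_f`, `area_bins`. Levels with zero basins produce a
#'   single row with `basin = NA`.
#' @export
fel_report <- function(grid, levels) {
  out <- lapply(levels, function(lv) {
    cb <- count_basins(grid, lv)
    if (cb$n_basins == 0) {
      tibble(level = lv, n_basins = 0L, basin = NA_integer_,
             min_f = NA_real_, area_bins = NA_integer_)
    } else {
      mutate(cb$basins, level = lv, n_basins = cb$n_basins,
             .before = 1)
    }
  })
  bind_rows(out)
}

#' @rdname tidytraj-tidiers
#' @method tidy fel_grid
#' @export
tidy.fel_grid <- function(x, ...) {
  grid <- expand.grid(i = seq_along(x$centers1), j = seq_along(x$centers2))
  tibble(
    ev1 = x$centers1[grid$i], ev2 = x$centers2[grid$j],
    count = x$counts[cbind(grid$i, grid$j)],
    free_energy = x$free_energy[cbind(grid$i, grid$j)]
  )
}

#' @rdname tidytraj-tidiers
#' @method glance fel_grid
#' @export
glance.fel_grid <- function(x, ...) {
  fin <- x$free_energy[is.finite(x$free_energy)]
  tibble(
    n_frames = x$n_frames, n_bins1 = nrow(x$counts), n_bins2 = ncol(x$counts),
    n_occupied = sum(x$counts > 0), temperature = x$temperature,
    f_max = max(fin)
  )
}
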