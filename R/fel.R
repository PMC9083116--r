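## Two-dimensional free-energy landscapes by Boltzmann inversion,
## F = -RT ln P, of the joint histogram of two order parameters, with
## grid-local basin detection.

#' Build a 2-D free-energy landscape from two order-parameter series
#'
#' The joint histogram of `(x, y)` over equal-width bins spanning the data
#' range is converted to probabilities P = counts / n_frames and inverted,
#' F = -RT ln P (kcal/mol, R = 1.9872e-3 kcal/mol/K), on visited bins.
#' F is shifted so its minimum over visited bins is 0; unvisited bins are
#' masked rather than assigned a sentinel (-RT ln 0 is undefined).
#'
#' @param series_x,series_y [op_series()] objects (or numeric vectors) of
#'   equal length.
#' @param n_bins integer vector of length 2, bins per axis (default
#'   `c(60, 60)`; at least 5 per axis).
#' @param temperature temperature in K for RT.  Defaults to the series'
#'   temperature label.
#' @return object of class `fel_grid`: list with `x_name`, `y_name`,
#'   `x_edges`, `y_edges`, `F` (nx x ny matrix, NA on masked bins), `mask`
#'   (TRUE = unvisited), `rt` (kcal/mol), `temperature`, `n_frames`.
#' @examples
#' x <- rep(c(0, 1), c(800, 200)); y <- rep(c(0, 1), c(800, 200))
#' g <- fel_2d(op_series("x", "", x, seq_along(x)),
#'             op_series("y", "", y, seq_along(y)),
#'             n_bins = c(5, 5), temperature = 300)
#' max(g$F, na.rm = TRUE)  # RT * ln 4
#' @export
fel_2d <- function(series_x, series_y, n_bins = c(60, 60),
                   temperature = NULL) {
  x <- if (inherits(series_x, "op_series")) series_x$values else as.numeric(series_x)
  y <- if (inherits(series_y, "op_series")) series_y$values else as.numeric(series_y)
  x_name <- if (inherits(series_x, "op_series")) series_x$name else "x"
  y_name <- if (inherits(series_y, "op_series")) series_y$name else "y"
  if (is.null(temperature)) {
    temperature <- if (inherits(series_x, "op_series")) series_x$temperature
                   else NA_real_
  }
  if (is.na(temperature)) stop("temperature (K) required to set RT")
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 100) stop("need at least 100 frames for a landscape")
  n_bins <- as.integer(rep_len(n_bins, 2))
  if (any(n_bins < 5)) stop("need at least 5 bins per axis")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("an axis has zero range (constant order parameter); ",
         "choose a different order-parameter pair")
  }
  x_edges <- seq(min(x), max(x), length.out = n_bins[1] + 1)
  y_edges <- seq(min(y), max(y), length.out = n_bins[2] + 1)
  ix <- pmin(pmax(findInterval(x, x_edges, rightmost.closed = TRUE), 1L),
             n_bins[1])
  iy <- pmin(pmax(findInterval(y, y_edges, rightmost.closed = TRUE), 1L),
             n_bins[2])
  counts <- matrix(tabulate(ix + (iy - 1L) * n_bins[1],
                            nbins = n_bins[1] * n_bins[2]),
                   n_bins[1], n_bins[2])
  n <- length(x)
  rt <- .R_KCAL * temperature
  P <- counts / n
  mask <- counts == 0L
  F <- matrix(NA_real_, n_bins[1], n_bins[2])
  F[!mask] <- -rt * log(P[!mask])
  F <- F - min(F, na.rm = TRUE)
  structure(list(x_name = x_name, y_name = y_name,
                 x_edges = x_edges, y_edges = y_edges,
                 F = F, mask = mask, rt = rt,
                 temperature = temperature, n_frames = n),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat(sprintf(
    "fel_grid %s vs %s: %d x %d bins (%d visited), RT = %.5f kcal/mol, %d frames\n",
    x$x_name, x$y_name, length(x$x_edges) - 1, length(x$y_edges) - 1,
    sum(!x$mask), x$rt, x$n_frames))
  invisible(x)
}

#' Locate free-energy basins on a landscape
#'
#' A basin is a visited bin whose F does not exceed any of its visited
#' 8-neighbours and lies at or below `depth_threshold`.  Plateaus of equal
#' F (mutually adjacent tied minima) are merged to a single basin reported
#' at the plateau's first bin in row-major order.  Basins are returned
#' sorted by F ascending (ties by row-major position).
#'
#' @param grid a [fel_2d()] grid.
#' @param depth_threshold report only basins with F at or below this value
#'   in kcal/mol (default 2).
#' @return data.frame with `ix`, `iy` (bin indices), `x`, `y` (bin
#'   centres), `F` (kcal/mol).
#' @export
find_minima <- function(grid, depth_threshold = 2) {
  stopifnot(inherits(grid, "fel_grid"))
  F <- grid$F
  nx <- nrow(F); ny <- ncol(F)
  if (all(grid$mask)) stop("grid has no visited bins")
  is_min <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      if (grid$mask[i, j] || F[i, j] > depth_threshold) next
      nb <- F[max(1, i - 1):min(nx, i + 1), max(1, j - 1):min(ny, j + 1)]
      if (all(F[i, j] <= nb, na.rm = TRUE)) is_min[i, j] <- TRUE
    }
  }
  cand <- which(is_min, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(data.frame(ix = integer(0), iy = integer(0),
                      x = numeric(0), y = numeric(0), F = numeric(0)))
  }
  # merge plateaus: connected (8-neighbour) tied candidates collapse to one
  comp <- seq_len(nrow(cand))
  repeat {
    changed <- FALSE
    for (a in seq_len(nrow(cand))) {
      for (b in seq_len(nrow(cand))) {
        if (comp[a] != comp[b] &&
            abs(cand[a, 1] - cand[b, 1]) <= 1 &&
            abs(cand[a, 2] - cand[b, 2]) <= 1 &&
            F[cand[a, 1], cand[a, 2]] == F[cand[b, 1], cand[b, 2]]) {
          comp[comp == comp[b]] <- comp[a]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  rowmajor <- (cand[, 2] - 1) * nx + cand[, 1]
  keep <- vapply(unique(comp), function(cc) {
    members <- which(comp == cc)
    members[which.min(rowmajor[members])]
  }, integer(1))
  cand <- cand[keep, , drop = FALSE]
  xc <- (grid$x_edges[-1] + grid$x_edges[-length(grid$x_edges)]) / 2
  yc <- (grid$y_edges[-1] + grid$y_edges[-length(grid$y_edges)]) / 2
  out <- data.frame(ix = cand[, 1], iy = cand[, 2],
                    x = xc[cand[, 1]], y = yc[cand[, 2]],
                    F = F[cand])
  out <- out[order(out$F, (out$iy - 1) * nx + out$ix), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Free-energy difference between two basins
#'
#' `F(basin_b) - F(basin_a)` in kcal/mol; antisymmetric in its arguments
#' and invariant to the landscape's global minimum shift.
#'
#' @param grid a [fel_2d()] grid.
#' @param basin_a,basin_b single rows of a [find_minima()] result (or any
#'   list/row with `ix`, `iy`).
#' @return numeric free-energy difference, kcal/mol.
#' @export
basin_delta_f <- function(grid, basin_a, basin_b) {
  stopifnot(inherits(grid, "fel_grid"))
  fa <- .basin_f(grid, basin_a)
  fb <- .basin_f(grid, basin_b)
  fb - fa
}

.basin_f <- function(grid, basin) {
  ix <- as.integer(basin[["ix"]][1])
  iy <- as.integer(basin[["iy"]][1])
  if (length(ix) != 1 || length(iy) != 1 ||
      is.na(ix) || is.na(iy) || ix < 1 || iy < 1 ||
      ix > nrow(grid$F) || iy > ncol(grid$F)) {
    stop("basin bin coordinates outside the grid")
  }
  if (grid$mask[ix, iy]) stop("basin refers to an unvisited (masked) bin")
  grid$F[ix, iy]
}
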