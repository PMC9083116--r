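## Dynamic cross-correlation matrices of residue (C-alpha) motion.

#' Dynamic cross-correlation matrix over a trajectory window
#'
#' With displacement vectors `dx_i = x_i - <x_i>` taken over the window
#' (after optional superposition of every frame onto the window's mean
#' structure, which removes global rotation/translation),
#' `C_ij = <dx_i . dx_j> / sqrt(<|dx_i|^2> <|dx_j|^2>)`: +1 for fully
#' correlated motion, -1 for anti-correlated.
#'
#' @param traj an [md_trajectory()].
#' @param window frame range `c(start, end)` (default: all frames); at
#'   least 10 frames.
#' @param align superpose frames onto the window-mean structure first
#'   (default TRUE).
#' @param selection atom indices (default: C-alpha atoms).
#' @return object of class `dccm_matrix`: list with `values` (n_sel x
#'   n_sel, symmetric, unit diagonal), `window`, `res_index`, `aligned`.
#'   Atoms immobile within the window get 0 off-diagonal entries and a
#'   warning.
#' @export
dccm_matrix <- function(traj, window = NULL, align = TRUE, selection = NULL) {
  if (is.null(selection)) selection <- select_atoms(traj$model, "calpha")
  nf <- n_frames(traj)
  if (is.null(window)) window <- c(1L, nf)
  window <- as.integer(window)
  if (length(window) != 2 || window[1] < 1 || window[2] > nf ||
      window[2] < window[1]) {
    stop("invalid frame window")
  }
  frames <- window[1]:window[2]
  if (length(frames) < 10) stop("window must contain at least 10 frames")

  X <- traj$coords[selection, , frames, drop = FALSE]
  if (align) {
    sub <- md_trajectory(
      structure_model(traj$model$atoms[selection, , drop = FALSE]),
      X, times = traj$times[frames], temperature = traj$temperature)
    X <- .iterated_mean(sub, seq_along(selection), passes = 2)$aligned
  }
  m <- apply(X, c(1, 2), mean)
  D <- X - array(m, dim = dim(X))
  n_sel <- length(selection)
  S <- matrix(0, n_sel, n_sel)
  for (k in 1:3) S <- S + tcrossprod(D[, k, ])
  v <- diag(S)
  zero <- v <= 1e-12
  if (any(zero)) {
    warning(sprintf("%d atom(s) immobile in window; rows/columns set to 0",
                    sum(zero)))
    v[zero] <- 1
  }
  C <- S / sqrt(outer(v, v))
  C[zero, ] <- 0
  C[, zero] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  structure(list(values = C, window = window,
                 res_index = traj$model$atoms$res_index[selection],
                 aligned = align),
            class = "dccm_matrix")
}

#' @export
print.dccm_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf(
    "dccm_matrix: %d residues, frames %d-%d, mean |off-diagonal| %.3f\n",
    nrow(x$values), x$window[1], x$window[2], mean(abs(off))))
  invisible(x)
}

#' DCCMs over several trajectory windows
#'
#' By default two windows are used, the first and last 10% of frames
#' (the start and the end of the run); alternatively `n_windows` equal
#' consecutive chunks, or explicit `ranges`.
#'
#' @param traj an [md_trajectory()].
#' @param n_windows optional number of equal consecutive windows.
#' @param ranges optional list of `c(start, end)` frame ranges
#'   (overrides `n_windows`).
#' @param edge_fraction fraction of frames in each default edge window
#'   (default 0.1).
#' @inheritParams dccm_matrix
#' @return list of [dccm_matrix()] objects, named by frame range.
#' @export
dccm_windows <- function(traj, n_windows = NULL, ranges = NULL,
                         edge_fraction = 0.1, align = TRUE,
                         selection = NULL) {
  nf <- n_frames(traj)
  if (is.null(ranges)) {
    if (is.null(n_windows)) {
      k <- max(10L, as.integer(floor(nf * edge_fraction)))
      ranges <- list(c(1L, k), c(nf - k + 1L, nf))
    } else {
      stopifnot(n_windows >= 1)
      bounds <- floor(seq(0, nf, length.out = n_windows + 1))
      ranges <- lapply(seq_len(n_windows),
                       function(i) c(bounds[i] + 1L, bounds[i + 1]))
    }
  }
  for (r in ranges) {
    if (r[2] < r[1]) stop("window has non-positive length")
  }
  out <- lapply(ranges, function(r) {
    dccm_matrix(traj, window = r, align = align, selection = selection)
  })
  names(out) <- vapply(ranges, function(r) sprintf("%d-%d", r[1], r[2]),
                       character(1))
  out
}
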