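## Solvent-accessible surface area by Shrake-Rupley quadrature.
##
## Test points are placed on each atom's solvent-expanded sphere with a
## deterministic golden-spiral rule, so results are reproducible without a
## random seed; a point is exposed when it lies outside every neighbouring
## atom's expanded sphere.

#' Deterministic quasi-uniform points on the unit sphere (golden spiral)
#'
#' @param n number of points.
#' @return `n x 3` matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area of one conformation
#'
#' Shrake-Rupley: each atom's area is
#' `(exposed points / total points) * 4 * pi * (r + probe)^2`.
#'
#' @param xyz `n x 3` coordinate matrix (Angstrom).
#' @param radii per-atom van der Waals radii (Angstrom), all positive.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4,
#'   water).
#' @param n_sphere_points quadrature points per atom (default 240;
#'   at least 50).
#' @return numeric vector of per-atom areas in Angstrom^2.
#' @examples
#' # isolated sphere: area is exact up to quadrature (here: exact)
#' sasa_per_atom(matrix(0, 1, 3), 1.5)  # 4*pi*2.9^2
#' @export
sasa_per_atom <- function(xyz, radii, probe_radius = 1.4,
                          n_sphere_points = 240) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(radii) == n, ncol(xyz) == 3)
  if (any(radii <= 0)) stop("all radii must be positive")
  if (n_sphere_points < 50) stop("n_sphere_points must be >= 50")
  S <- golden_spiral_points(n_sphere_points)
  R <- radii + probe_radius
  # neighbour candidates from pairwise distances
  d2 <- as.matrix(stats::dist(xyz))^2
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2)
    nb <- nb[nb != i]
    if (length(nb) == 0) {
      exposed <- n_sphere_points
    } else {
      pts <- S * R[i]
      pts <- sweep(pts, 2, xyz[i, ], `+`)
      covered <- rep(FALSE, n_sphere_points)
      nbc <- xyz[nb, , drop = FALSE]
      # squared distances points x neighbours
      pd2 <- outer(rowSums(pts^2), rowSums(nbc^2), `+`) -
        2 * tcrossprod(pts, nbc)
      covered <- rowSums(sweep(pd2, 2, R[nb]^2, `<`)) > 0
      exposed <- sum(!covered)
    }
    areas[i] <- exposed / n_sphere_points * 4 * pi * R[i]^2
  }
  areas
}

#' Total SASA time series of a trajectory
#'
#' Whole-structure SASA per frame, computed over heavy atoms (hydrogens
#' are ignored both as surfaces and as occluders, the convention of
#' heavy-atom SASA calculations).
#'
#' @param traj an [md_trajectory()].
#' @param probe_radius probe radius in Angstrom (default 1.4).
#' @param n_sphere_points quadrature points per atom (default 240).
#' @param stride evaluate every `stride`-th frame (default 1); the
#'   returned series carries the matching subset of frame times.
#' @return an [op_series()] named `"sasa"` in Angstrom^2.
#' @export
sasa_series <- function(traj, probe_radius = 1.4, n_sphere_points = 240,
                        stride = 1) {
  heavy <- select_atoms(traj$model, "heavy")
  radii <- traj$model$atoms$radius[heavy]
  frames <- seq(1, n_frames(traj), by = stride)
  vals <- vapply(frames, function(f) {
    x <- traj$coords[heavy, , f, drop = FALSE]
    dim(x) <- dim(x)[1:2]
    sum(sasa_per_atom(x, radii, probe_radius, n_sphere_points))
  }, numeric(1))
  op_series("sasa", "A^2", vals, traj$times[frames], traj$temperature)
}

#' Side-chain SASA time series of one residue
#'
#' Sum of per-atom SASA over the residue's heavy side-chain atoms,
#' computed in the context of the whole structure (all heavy atoms
#' occlude).  Glycine, having no heavy side-chain atoms, is an error.
#'
#' @param traj an [md_trajectory()].
#' @param residue internal residue index (1-based).
#' @inheritParams sasa_series
#' @return an [op_series()] named `"sidechain_sasa"` in Angstrom^2.
#' @export
residue_sidechain_sasa_series <- function(traj, residue, probe_radius = 1.4,
                                          n_sphere_points = 240, stride = 1) {
  sc <- withCallingHandlers(
    select_atoms(traj$model, "sidechain", residue = residue),
    warning = function(w) invokeRestart("muffleWarning"))
  if (length(sc) == 0) {
    stop(sprintf("residue %d has no heavy side-chain atoms (glycine?)",
                 residue))
  }
  heavy <- select_atoms(traj$model, "heavy")
  radii <- traj$model$atoms$radius[heavy]
  pos <- match(sc, heavy)
  frames <- seq(1, n_frames(traj), by = stride)
  vals <- vapply(frames, function(f) {
    x <- traj$coords[heavy, , f, drop = FALSE]
    dim(x) <- dim(x)[1:2]
    sum(sasa_per_atom(x, radii, probe_radius, n_sphere_points)[pos])
  }, numeric(1))
  op_series("sidechain_sasa", "A^2", vals, traj$times[frames],
            traj$temperature)
}
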