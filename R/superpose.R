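## Rigid-body superposition (Kabsch algorithm) and the order parameters
## built on it: RMSD time series and per-residue RMSF.

#' Optimal rigid superposition of two point sets (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the (weighted)
#' RMSD between `mobile` and `reference`.  The rotation is obtained from
#' the SVD of the weighted covariance matrix with the usual determinant
#' correction, so a reflection is never returned.
#'
#' @param reference n x 3 matrix (Angstrom).
#' @param mobile n x 3 matrix, same n.
#' @param weights optional non-negative weights of length n.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   the fitted mobile set is `mobile %*% t(rotation) + translation`),
#'   `rmsd` (Angstrom, at the optimum), and `unique` (FALSE for
#'   degenerate/collinear point sets, where the optimal rotation is not
#'   unique although the RMSD still is).
#' @examples
#' ref <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch_superpose(ref, ref + 5)  # pure translation
#' fit$rmsd  # ~0
#' @export
kabsch_superpose <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  n <- nrow(reference)
  if (n < 1) stop("need at least one point")
  if (!all(dim(reference) == dim(mobile)) || ncol(reference) != 3) {
    stop("reference and mobile must be matching n x 3 matrices")
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  cref <- colSums(reference * w)
  cmob <- colSums(mobile * w)
  P <- sweep(mobile, 2, cmob)      # centred mobile
  Q <- sweep(reference, 2, cref)   # centred reference
  H <- crossprod(P * w, Q)         # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  # rotation unique iff the two smallest singular values are distinct from
  # zero-rank degeneracy (collinear or near-degenerate point sets)
  tol <- max(sv$d[1], 1) * 1e-9
  unique_rot <- n >= 3 && sv$d[2] > tol
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(cref - R %*% cmob),
       rmsd = rmsd, unique = unique_rot)
}

# superpose frame coords onto reference over `fit_idx`, return transformed
# full coordinate matrix
.apply_fit <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' RMSD time series against a reference frame
#'
#' Each frame is optimally superposed onto the reference over the given
#' atom selection (Kabsch), and the post-fit RMSD over that selection is
#' reported in Angstrom.
#'
#' @param traj an [md_trajectory()].
#' @param reference reference coordinates: a frame index into `traj`
#'   (default 1) or an `n_atoms x 3` matrix over the full topology.
#' @param selection atom index vector (e.g. from [select_atoms()]);
#'   default C-alpha atoms.
#' @return an [op_series()] named `"rmsd"` in Angstrom.
#' @export
rmsd_series <- function(traj, reference = 1, selection = NULL) {
  if (is.null(selection)) selection <- select_atoms(traj$model, "calpha")
  if (length(selection) == 0) stop("empty atom selection")
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  refsel <- ref[selection, , drop = FALSE]
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(f) {
    kabsch_superpose(refsel, traj$coords[selection, , f])$rmsd
  }, numeric(1))
  op_series("rmsd", "A", vals, traj$times, traj$temperature)
}

# mean structure over selected atoms with iterative alignment
.iterated_mean <- function(traj, selection, passes = 2) {
  X <- traj$coords[selection, , , drop = FALSE]
  nf <- dim(X)[3]
  m <- apply(X, c(1, 2), mean)
  for (p in seq_len(passes)) {
    aligned <- X
    for (f in seq_len(nf)) {
      fit <- kabsch_superpose(m, X[, , f])
      aligned[, , f] <- .apply_fit(X[, , f], fit)
    }
    m <- apply(aligned, c(1, 2), mean)
    X <- aligned
  }
  list(mean = m, aligned = X)
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of each C-alpha atom about its mean position.  With `align = TRUE`
#' every frame is first superposed onto the mean structure, which is
#' itself refined iteratively (align, re-average; 2 passes); with
#' `reference = "first"` frames are aligned onto frame 1 instead.
#'
#' @param traj an [md_trajectory()] with at least 2 frames.
#' @param align superpose frames before measuring fluctuations
#'   (default TRUE).
#' @param reference `"mean"` (iterated mean structure, default) or
#'   `"first"`.
#' @return data.frame with `res_index`, `resno`, `rmsf` (Angstrom).
#' @export
rmsf_per_residue <- function(traj, align = TRUE,
                             reference = c("mean", "first")) {
  reference <- match.arg(reference)
  if (n_frames(traj) < 2) stop("RMSF requires at least 2 frames")
  sel <- select_atoms(traj$model, "calpha")
  if (align) {
    if (reference == "mean") {
      X <- .iterated_mean(traj, sel, passes = 2)$aligned
    } else {
      X <- traj$coords[sel, , , drop = FALSE]
      ref <- X[, , 1]
      for (f in seq_len(dim(X)[3])) {
        fit <- kabsch_superpose(ref, X[, , f])
        X[, , f] <- .apply_fit(X[, , f], fit)
      }
    }
  } else {
    X <- traj$coords[sel, , , drop = FALSE]
  }
  m <- apply(X, c(1, 2), mean)
  dev2 <- apply((X - array(m, dim = dim(X)))^2, c(1, 3), sum)
  rmsf <- sqrt(rowMeans(dev2))
  data.frame(res_index = traj$model$atoms$res_index[sel],
             resno = traj$model$atoms$resno[sel],
             rmsf = rmsf)
}
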