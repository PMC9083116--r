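## Scalar order parameters describing folding state: radius of gyration,
## fraction of native contacts, and intraprotein hydrogen-bond counts.

#' Radius-of-gyration time series
#'
#' Rg = sqrt( sum_k m_k |x_k - xbar|^2 / sum_k m_k ), with `xbar` the
#' (mass-weighted) centroid of the selection.  Rotation/translation of a
#' frame leaves Rg unchanged; no superposition is performed.
#'
#' @param traj an [md_trajectory()].
#' @param selection atom indices (default: all heavy atoms).
#' @param mass_weighted use atomic masses as weights (default TRUE);
#'   otherwise unit weights.
#' @return an [op_series()] named `"rg"` in Angstrom.
#' @export
radius_of_gyration_series <- function(traj, selection = NULL,
                                      mass_weighted = TRUE) {
  if (is.null(selection)) selection <- select_atoms(traj$model, "heavy")
  if (length(selection) == 0) stop("empty atom selection")
  m <- if (mass_weighted) traj$model$atoms$mass[selection] else
    rep(1, length(selection))
  if (sum(m) <= 0) stop("total mass of selection is zero")
  w <- m / sum(m)
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(f) {
    xyz <- traj$coords[selection, , f, drop = FALSE]
    ctr <- colSums(xyz * w)
    sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)))
  }, numeric(1))
  op_series("rg", "A", vals, traj$times, traj$temperature)
}

#' Native-contact set of a reference frame
#'
#' A native contact is a pair of heavy atoms from two residues separated
#' by at least `min_sequence_separation` in sequence whose distance in the
#' reference frame is at most `cutoff`.  The default cutoff of 4 Angstrom
#' re-evaluated per frame defines the fraction of native contacts Nc; the
#' minimum sequence separation (default 3) excludes trivially permanent
#' neighbour contacts that would inflate the Nc floor.
#'
#' @param traj an [md_trajectory()].
#' @param reference_frame frame index defining the native state (default 1),
#'   or an `n_atoms x 3` coordinate matrix.
#' @param cutoff contact distance cutoff in Angstrom (default 4.0).
#' @param min_sequence_separation minimum |residue i - residue j|
#'   (default 3).
#' @return object of class `native_contact_set`: list with `pairs`
#'   (n_pairs x 2 heavy-atom indices, first column < second), `n_pairs`,
#'   `cutoff`, `min_sequence_separation`, `reference_frame`.  Errors if no
#'   contact qualifies (nothing to normalise by).
#' @export
native_contacts <- function(traj, reference_frame = 1, cutoff = 4.0,
                            min_sequence_separation = 3) {
  stopifnot(cutoff > 0, min_sequence_separation >= 1)
  ref <- if (is.matrix(reference_frame)) reference_frame else
    frame_coords(traj, reference_frame)
  heavy <- select_atoms(traj$model, "heavy")
  res <- traj$model$atoms$res_index[heavy]
  xyz <- ref[heavy, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(res, res, `-`))
  hit <- which(d <= cutoff & sep >= min_sequence_separation, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  if (nrow(hit) == 0) {
    stop("no native contacts found in the reference frame; ",
         "cannot define an Nc normalisation")
  }
  structure(list(pairs = cbind(heavy[hit[, 1]], heavy[hit[, 2]]),
                 n_pairs = nrow(hit),
                 cutoff = cutoff,
                 min_sequence_separation = min_sequence_separation,
                 reference_frame = if (is.matrix(reference_frame)) NA_integer_
                                   else as.integer(reference_frame)),
            class = "native_contact_set")
}

#' @export
print.native_contact_set <- function(x, ...) {
  cat(sprintf(
    "native_contact_set: %d heavy-atom pairs (cutoff %.2f A, |dres| >= %d)\n",
    x$n_pairs, x$cutoff, x$min_sequence_separation))
  invisible(x)
}

#' Fraction-of-native-contacts time series
#'
#' Per frame, the fraction of native pairs whose distance is at most
#' `cutoff * tolerance_factor`.  With the default `tolerance_factor = 1`
#' the 4-Angstrom contact criterion is strictly re-evaluated each frame,
#' so the reference frame itself scores exactly 1.
#'
#' @param traj an [md_trajectory()].
#' @param native a [native_contacts()] set.
#' @param tolerance_factor multiplier on the native cutoff when
#'   re-evaluating contacts per frame (default 1.0).
#' @return an [op_series()] named `"nc"` with values in [0, 1].
#' @export
nc_fraction_series <- function(traj, native, tolerance_factor = 1.0) {
  stopifnot(inherits(native, "native_contact_set"), tolerance_factor > 0)
  thr2 <- (native$cutoff * tolerance_factor)^2
  nf <- n_frames(traj)
  counts <- numeric(nf)
  P <- native$pairs
  for (p in seq_len(native$n_pairs)) {
    i <- P[p, 1]; j <- P[p, 2]
    d2 <- (traj$coords[i, 1, ] - traj$coords[j, 1, ])^2 +
          (traj$coords[i, 2, ] - traj$coords[j, 2, ])^2 +
          (traj$coords[i, 3, ] - traj$coords[j, 3, ])^2
    counts <- counts + (d2 <= thr2)
  }
  op_series("nc", "fraction", counts / native$n_pairs, traj$times,
            traj$temperature)
}

#' Intraprotein backbone hydrogen-bond count per frame
#'
#' Counts backbone N(H)...O=C donor-acceptor pairs between residues at
#' least `min_sequence_separation` apart.  The geometric criterion is
#' N...O distance <= `distance_cutoff`; when the structure carries amide
#' hydrogens a D-H...A angle >= `angle_min` degrees is additionally
#' required, otherwise the amide H is reconstructed from the backbone
#' (1.01 Angstrom from N, anti to the preceding carbonyl) and the same
#' angle test applied.  Residue 1 has no reconstructable H and never
#' donates in that case.
#'
#' @param traj an [md_trajectory()].
#' @param distance_cutoff N...O cutoff in Angstrom (default 3.5).
#' @param angle_min minimum D-H...A angle in degrees (default 120).
#' @param min_sequence_separation minimum |residue i - residue j|
#'   (default 2).
#' @return an [op_series()] named `"hbonds"` with integer counts.
#' @export
hbond_count_series <- function(traj, distance_cutoff = 3.5, angle_min = 120,
                               min_sequence_separation = 2) {
  a <- traj$model$atoms
  nres <- traj$model$n_residues
  n_idx <- o_idx <- h_idx <- rep(NA_integer_, nres)
  for (r in seq_len(nres)) {
    ai <- traj$model$res_atoms[[r]]
    nm <- a$name[ai]
    n_idx[r] <- ai[match("N", nm)]
    o_idx[r] <- ai[match("O", nm)]
    h_idx[r] <- ai[match(TRUE, nm %in% c("H", "HN"))]
  }
  if (all(is.na(n_idx)) || all(is.na(o_idx))) {
    stop("structure has no backbone N/O atoms")
  }
  have_h <- any(!is.na(h_idx))
  sep_ok <- abs(outer(seq_len(nres), seq_len(nres), `-`)) >=
    min_sequence_separation
  nf <- n_frames(traj)
  counts <- integer(nf)
  cosmin <- cos(angle_min * pi / 180)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f, drop = TRUE]
    H <- matrix(NA_real_, nres, 3)
    if (have_h) {
      ok <- !is.na(h_idx)
      H[ok, ] <- xyz[h_idx[ok], , drop = FALSE]
    } else {
      H <- .reconstruct_amide_h(xyz, n_idx, traj$model)
    }
    Np <- xyz[n_idx, , drop = FALSE]
    Op <- xyz[o_idx, , drop = FALSE]
    # distance matrix donors (rows, N of residue d) x acceptors (cols, O of a)
    d2 <- outer(rowSums(Np^2), rowSums(Op^2), `+`) - 2 * tcrossprod(Np, Op)
    cand <- which(d2 <= distance_cutoff^2 & sep_ok, arr.ind = TRUE)
    if (nrow(cand)) {
      keep <- !is.na(n_idx[cand[, 1]]) & !is.na(o_idx[cand[, 2]])
      cand <- cand[keep, , drop = FALSE]
    }
    cnt <- 0L
    for (k in seq_len(nrow(cand))) {
      dres <- cand[k, 1]; ares <- cand[k, 2]
      h <- H[dres, ]
      if (anyNA(h)) next  # no donor hydrogen (chain start)
      v1 <- xyz[n_idx[dres], ] - h
      v2 <- Op[ares, ] - h
      ca <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      # angle(N-H...O) >= angle_min  <=>  cos(angle) <= cos(angle_min)
      if (ca <= cosmin) cnt <- cnt + 1L
    }
    counts[f] <- cnt
  }
  op_series("hbonds", "count", counts, traj$times, traj$temperature)
}

# amide H positions reconstructed per residue: 1.01 A from N, in the
# direction (C_prev - O_prev); residue 1 (and residues missing backbone
# atoms) get NA rows
.reconstruct_amide_h <- function(xyz, n_idx, model) {
  a <- model$atoms
  nres <- model$n_residues
  H <- matrix(NA_real_, nres, 3)
  c_idx <- o_idx <- rep(NA_integer_, nres)
  for (r in seq_len(nres)) {
    ai <- model$res_atoms[[r]]
    nm <- a$name[ai]
    c_idx[r] <- ai[match("C", nm)]
    o_idx[r] <- ai[match("O", nm)]
  }
  for (r in 2:nres) {
    if (is.na(n_idx[r]) || is.na(c_idx[r - 1]) || is.na(o_idx[r - 1])) next
    v <- xyz[c_idx[r - 1], ] - xyz[o_idx[r - 1], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) next
    H[r, ] <- xyz[n_idx[r], ] + 1.01 * v / nv
  }
  H
}
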