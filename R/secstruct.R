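## Per-frame secondary-structure assignment with a simplified
## Kabsch-Sander scheme: backbone H-bonds are scored with the classic
## electrostatic dipole model, E = 27.888 * (1/rON + 1/rCH - 1/rOH - 1/rCN)
## kcal/mol, a bond being declared below -0.5 kcal/mol; helices, bridges,
## turns and bends are then read off the bond pattern.  Amide hydrogens are
## reconstructed from the backbone when the structure carries none.

.SS_CODES <- c(H = "alpha helix", G = "3-10 helix", I = "pi helix",
               E = "extended strand", B = "isolated bridge", T = "turn",
               S = "bend", C = "coil")
.KS_COUPLING <- 27.888   # q1*q2*f, kcal * Angstrom / mol
.KS_BOND_E <- -0.5       # kcal/mol
.KS_CLAMP <- -9.9

# per-residue backbone atom indices; NA where missing
.backbone_index <- function(model) {
  nres <- model$n_residues
  out <- matrix(NA_integer_, nres, 5,
                dimnames = list(NULL, c("N", "CA", "C", "O", "H")))
  a <- model$atoms
  for (r in seq_len(nres)) {
    ai <- model$res_atoms[[r]]
    nm <- a$name[ai]
    out[r, "N"] <- ai[match("N", nm)]
    out[r, "CA"] <- ai[match("CA", nm)]
    out[r, "C"] <- ai[match("C", nm)]
    out[r, "O"] <- ai[match("O", nm)]
    out[r, "H"] <- ai[match(TRUE, nm %in% c("H", "HN"))]
  }
  out
}

# Kabsch-Sander energy matrix: E[a, d] = energy of the bond with acceptor
# C=O of residue a and donor N-H of residue d; +Inf where undefined
.ks_energy_matrix <- function(xyz, model, bb = NULL) {
  if (is.null(bb)) bb <- .backbone_index(model)
  nres <- model$n_residues
  get <- function(col) {
    out <- matrix(NA_real_, nres, 3)
    ok <- !is.na(bb[, col])
    out[ok, ] <- xyz[bb[ok, col], , drop = FALSE]
    out
  }
  Np <- get("N"); Cp <- get("C"); Op <- get("O")
  Hp <- get("H")
  if (all(is.na(Hp))) {
    Hp <- .reconstruct_amide_h(xyz, bb[, "N"], model)
  }
  dmat <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    sqrt(pmax(d2, 0))
  }
  rON <- dmat(Op, Np); rCH <- dmat(Cp, Hp)
  rOH <- dmat(Op, Hp); rCN <- dmat(Cp, Np)
  E <- .KS_COUPLING * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  E[rON < 0.5 | rCH < 0.5 | rOH < 0.5 | rCN < 0.5] <- .KS_CLAMP
  E[is.na(E)] <- Inf
  sep <- abs(outer(seq_len(nres), seq_len(nres), `-`))
  E[sep < 2] <- Inf
  E
}

#' Kabsch-Sander backbone hydrogen-bond energy for one residue pair
#'
#' Electrostatic dipole-dipole model between the donor's N-H and the
#' acceptor's C=O: `E = 27.888 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol
#' with distances in Angstrom; a hydrogen bond is declared when
#' `E < -0.5` kcal/mol.  The amide hydrogen is reconstructed from the
#' backbone (1.01 Angstrom from N, anti to the preceding carbonyl) when
#' the structure carries none.
#'
#' @param traj an [md_trajectory()].
#' @param donor,acceptor internal residue indices (donor contributes N-H,
#'   acceptor C=O); must differ by at least 2.
#' @param frame frame index (default 1).
#' @return list with `energy` (kcal/mol, NA when backbone atoms are
#'   missing, with a warning) and `bond` (logical).
#' @export
backbone_hbond_energy <- function(traj, donor, acceptor, frame = 1) {
  model <- traj$model
  if (donor == acceptor) stop("donor and acceptor must differ")
  if (abs(donor - acceptor) < 2) {
    stop("donor and acceptor must be separated by at least 2 residues")
  }
  stopifnot(donor >= 1, donor <= model$n_residues,
            acceptor >= 1, acceptor <= model$n_residues)
  bb <- .backbone_index(model)
  if (anyNA(bb[c(donor, acceptor), c("N", "CA", "C", "O")])) {
    warning("missing backbone atom(s); no hydrogen bond assigned")
    return(list(energy = NA_real_, bond = FALSE))
  }
  E <- .ks_energy_matrix(frame_coords(traj, frame), model, bb)
  e <- E[acceptor, donor]
  if (!is.finite(e)) {
    warning("hydrogen-bond energy undefined for this pair ",
            "(missing donor hydrogen?)")
    return(list(energy = NA_real_, bond = FALSE))
  }
  list(energy = e, bond = e < .KS_BOND_E)
}

# secondary-structure codes for one conformation
.ss_assign <- function(xyz, model, bb = NULL) {
  if (is.null(bb)) bb <- .backbone_index(model)
  nres <- model$n_residues
  complete <- rowSums(is.na(bb[, c("N", "CA", "C", "O"), drop = FALSE])) == 0
  if (sum(complete) < 5) {
    warning("fewer than 5 residues with complete backbone; all coil")
    return(rep("C", nres))
  }
  E <- .ks_energy_matrix(xyz, model, bb)
  hb <- E < .KS_BOND_E          # hb[i, j]: CO(i) <- NH(j)
  codes <- rep("C", nres)

  # S: bend, CA(i-2) -> CA(i) -> CA(i+2) direction change > 70 degrees
  ca <- matrix(NA_real_, nres, 3)
  ok <- !is.na(bb[, "CA"])
  ca[ok, ] <- xyz[bb[ok, "CA"], , drop = FALSE]
  for (i in 3:(nres - 2)) {
    v1 <- ca[i, ] - ca[i - 2, ]
    v2 <- ca[i + 2, ] - ca[i, ]
    if (anyNA(v1) || anyNA(v2)) next
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    if (acos(pmin(pmax(cosang, -1), 1)) > 70 * pi / 180) codes[i] <- "S"
  }

  # T: residues strictly inside any n-turn (CO(i) <- NH(i+n), n = 3,4,5)
  turn <- function(n) {
    i <- seq_len(nres - n)
    i[hb[cbind(i, i + n)]]
  }
  for (n in c(3, 4, 5)) {
    for (i in turn(n)) codes[(i + 1):(i + n - 1)] <- "T"
  }

  # bridges (parallel or antiparallel), then E for ladders / B isolated
  bridged <- rep(FALSE, nres)
  partner <- vector("list", nres)
  for (i in 2:(nres - 1)) {
    for (j in 2:(nres - 1)) {
      if (j < i + 3) next
      par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) {
        bridged[i] <- bridged[j] <- TRUE
        partner[[i]] <- c(partner[[i]], j)
        partner[[j]] <- c(partner[[j]], i)
      }
    }
  }
  for (i in which(bridged)) {
    ladder <- (i > 1 && bridged[i - 1]) || (i < nres && bridged[i + 1])
    codes[i] <- if (ladder) "E" else "B"
  }

  # helices from >= 2 consecutive n-turns; overwrite order encodes the
  # priority H > G > I > E > B > T > S > C
  mark_helix <- function(n, code) {
    i <- 2:(nres - n)
    sel <- i[hb[cbind(i - 1, i - 1 + n)] & hb[cbind(i, i + n)]]
    for (s in sel) codes[s:(s + n - 1)] <<- code
  }
  mark_helix(5, "I")
  mark_helix(3, "G")
  mark_helix(4, "H")

  # chain termini lack the neighbours/partners for helix or strand
  codes[c(1, nres)][codes[c(1, nres)] %in% c("H", "E")] <- "C"
  codes
}

#' Assign secondary structure to one frame
#'
#' @param traj an [md_trajectory()].
#' @param frame frame index (default 1).
#' @return character vector of per-residue codes in
#'   `H, G, I, E, B, T, S, C` (helix, 3-10 helix, pi helix, strand,
#'   isolated bridge, turn, bend, coil).
#' @export
assign_frame <- function(traj, frame = 1) {
  .ss_assign(frame_coords(traj, frame), traj$model)
}

#' Secondary-structure timeline of a trajectory
#'
#' @param traj an [md_trajectory()].
#' @param stride assign every `stride`-th frame (default 1).
#' @return object of class `ss_timeline`: character matrix
#'   `n_frames x n_residues` with attributes `times` and `legend`.
#' @export
ss_timeline <- function(traj, stride = 1) {
  bb <- .backbone_index(traj$model)
  frames <- seq(1, n_frames(traj), by = stride)
  codes <- t(vapply(frames, function(f) {
    .ss_assign(traj$coords[, , f, drop = TRUE], traj$model, bb)
  }, character(traj$model$n_residues)))
  structure(codes, class = "ss_timeline", times = traj$times[frames],
            legend = .SS_CODES)
}

#' Per-frame secondary-structure content
#'
#' @param timeline an [ss_timeline()].
#' @return data.frame with `time_ps` and one fraction column per code;
#'   fractions sum to 1 in every frame.
#' @export
ss_content_series <- function(timeline) {
  stopifnot(inherits(timeline, "ss_timeline"))
  codes <- names(.SS_CODES)
  frac <- vapply(codes, function(cc) rowMeans(unclass(timeline) == cc),
                 numeric(nrow(timeline)))
  if (nrow(timeline) == 1) frac <- matrix(frac, nrow = 1,
                                          dimnames = list(NULL, codes))
  out <- data.frame(time_ps = attr(timeline, "times"), frac,
                    check.names = FALSE)
  out
}
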