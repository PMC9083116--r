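# Independent oracles and fixture builders used across the suite.

# Horn's quaternion method for optimal-superposition RMSD; independent of
# the package's SVD-based Kabsch implementation.
quaternion_rmsd <- function(ref, mob) {
  n <- nrow(ref)
  rc <- sweep(ref, 2, colMeans(ref))
  mc <- sweep(mob, 2, colMeans(mob))
  M <- crossprod(mc, rc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  G <- sum(rc^2) + sum(mc^2)
  sqrt(max(0, G - 2 * lam) / n)
}

# brute-force RMSD by scanning a rotation grid (Euler angles), refined
# around the best cell; slow but assumption-free
brute_rotation_rmsd <- function(ref, mob, coarse = 24) {
  rc <- sweep(ref, 2, colMeans(ref))
  mc <- sweep(mob, 2, colMeans(mob))
  rotmat <- function(a, b, g) {
    Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rz2
  }
  eval_r <- function(a, b, g) {
    sqrt(mean(rowSums((mc %*% t(rotmat(a, b, g)) - rc)^2)))
  }
  best <- c(0, 0, 0); best_v <- Inf
  gr <- seq(0, 2 * pi, length.out = coarse + 1)[-1]
  grb <- seq(0, pi, length.out = coarse %/% 2 + 1)
  for (a in gr) for (b in grb) for (g in gr) {
    v <- eval_r(a, b, g)
    if (v < best_v) { best_v <- v; best <- c(a, b, g) }
  }
  step <- 2 * pi / coarse
  for (it in 1:30) {
    step <- step / 2
    for (da in c(-step, 0, step)) for (db in c(-step, 0, step))
      for (dg in c(-step, 0, step)) {
        v <- eval_r(best[1] + da, best[2] + db, best[3] + dg)
        if (v < best_v) { best_v <- v; best <- best + c(da, db, dg) }
      }
  }
  best_v
}

# brute-force Nc recomputation: per frame, full heavy-atom distance matrix
# and direct counting against the native pair list
brute_force_nc <- function(traj, native) {
  P <- native$pairs
  thr <- native$cutoff
  vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- traj$coords[, , f, drop = TRUE]
    d <- sqrt(rowSums((xyz[P[, 1], , drop = FALSE] -
                       xyz[P[, 2], , drop = FALSE])^2))
    mean(d <= thr)
  }, numeric(1))
}

# backbone (+CB) model from build_backbone output
backbone_model <- function(bb, n, resnames = rep("ALA", n), with_cb = TRUE) {
  at <- list(); xyz <- list(); s <- 0L
  for (r in seq_len(n)) {
    nm <- c("N", "CA", "C", "O")
    co <- rbind(bb$N[r, ], bb$CA[r, ], bb$C[r, ], bb$O[r, ])
    if (with_cb && resnames[r] != "GLY") {
      nm <- c(nm, "CB")
      co <- rbind(co, mdunfold:::place_cb(bb$N[r, ], bb$CA[r, ], bb$C[r, ]))
    }
    at[[r]] <- data.frame(serial = s + seq_along(nm), name = nm,
                          resname = resnames[r], chain = "A", resno = r,
                          element = mdunfold:::infer_element(nm),
                          stringsAsFactors = FALSE)
    s <- s + length(nm)
    xyz[[r]] <- co
  }
  list(model = structure_model(do.call(rbind, at)),
       xyz = do.call(rbind, xyz))
}

# ideal polyalanine alpha-helix trajectory fixture
helix_fixture <- function(n = 15, with_cb = TRUE) {
  bb <- mdunfold:::build_backbone(rep(-57, n), rep(-47, n))
  fx <- backbone_model(bb, n, with_cb = with_cb)
  md_trajectory(fx$model, fx$xyz)
}

# ideal antiparallel beta-hairpin trajectory fixture (strands 2:8 / 11:17)
hairpin_fixture <- function(with_cb = TRUE) {
  n <- 18
  phi <- rep(-80, n); psi <- rep(130, n)
  phi[c(2:8, 11:17)] <- -93; psi[c(2:8, 11:17)] <- 107
  phi[9:10] <- c(27, 140); psi[9:10] <- c(38, -38)
  bb <- mdunfold:::build_backbone(phi, psi)
  fx <- backbone_model(bb, n, with_cb = with_cb)
  md_trajectory(fx$model, fx$xyz)
}

# simplified (3-state) secondary structure from the mdtraj reference
# implementation, via the system python; rows = frames
mdtraj_dssp <- function(traj) {
  pdb <- tempfile(fileext = ".pdb")
  on.exit(unlink(pdb))
  write_multimodel_pdb(traj, pdb)
  py <- sprintf(paste0(
    "import mdtraj\n",
    "t = mdtraj.load('%s')\n",
    "ss = mdtraj.compute_dssp(t, simplified=True)\n",
    "for row in ss:\n",
    "    print(''.join(row))\n"), pdb)
  out <- system2("python", "-", stdout = TRUE, stderr = FALSE, input = py)
  do.call(rbind, strsplit(out, ""))
}

# collapse the 8-code alphabet to the simplified H/E/C alphabet
simplify_ss <- function(codes) {
  ifelse(codes %in% c("H", "G", "I"), "H",
         ifelse(codes %in% c("E", "B"), "E", "C"))
}

# CA-only model: one atom per residue at the given coordinates
ca_only_model <- function(n) {
  structure_model(data.frame(
    serial = seq_len(n), name = "CA", resname = "ALA", chain = "A",
    resno = seq_len(n), element = "C", stringsAsFactors = FALSE))
}

# hand-assembled FEL grid for basin-detection tests
manual_fel_grid <- function(F, rt = 0.59616) {
  structure(list(x_name = "x", y_name = "y",
                 x_edges = seq(0, nrow(F)), y_edges = seq(0, ncol(F)),
                 F = F, mask = is.na(F), rt = rt, temperature = 300,
                 n_frames = 1000L),
            class = "fel_grid")
}
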