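## Internal geometry helpers: placing atoms from internal coordinates
## (bond length, bond angle, torsion) and building idealised peptide
## backbones from a phi/psi profile.  Used by the synthetic-trajectory
## generator and the test fixtures.

# place atom D given A-B-C such that |CD| = bond, angle(B,C,D) = angle
# (degrees) and torsion(A,B,C,D) = torsion (degrees)
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# ideal peptide internal coordinates (Angstrom / degrees)
.BOND_N_CA <- 1.458
.BOND_CA_C <- 1.525
.BOND_C_N <- 1.329
.BOND_C_O <- 1.231
.ANGLE_N_CA_C <- 111.2
.ANGLE_CA_C_N <- 116.2
.ANGLE_C_N_CA <- 121.7
.ANGLE_CA_C_O <- 120.8

# build backbone N, CA, C, O for a chain from per-residue (phi, psi);
# omega fixed at 180.  Returns a list of n x 3 matrices N, CA, C, O.
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BOND_N_CA, 0, 0)
  C[1, ] <- place_atom(c(0, 1, 0), N[1, ], CA[1, ], .BOND_CA_C,
                       .ANGLE_N_CA_C, phi[1])
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], .BOND_C_N,
                         .ANGLE_CA_C_N, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], .BOND_N_CA,
                          .ANGLE_C_N_CA, 180)  # omega
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], .BOND_CA_C,
                         .ANGLE_N_CA_C, phi[i])
  }
  for (i in 1:n) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], .BOND_C_O,
                         .ANGLE_CA_C_O, psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# beta-carbon from the backbone frame of one residue
place_cb <- function(n, ca, c) {
  place_atom(c, n, ca, 1.53, 110.4, 122.6)
}

# idealised tryptophan-like side chain (CB + 9 indole-ring heavy atoms)
# grown from one residue's backbone; returns 10 x 3 matrix with rownames
place_trp_sidechain <- function(n, ca, c) {
  cb <- place_cb(n, ca, c)
  cg <- place_atom(n, ca, cb, 1.50, 114.0, -60)
  cd1 <- place_atom(ca, cb, cg, 1.37, 127.0, 90)
  cd2 <- place_atom(ca, cb, cg, 1.43, 127.0, -90)
  ne1 <- place_atom(cb, cg, cd1, 1.38, 110.0, 180)
  ce2 <- place_atom(cb, cg, cd2, 1.41, 107.0, 180)
  ce3 <- place_atom(cb, cg, cd2, 1.40, 133.5, 0)
  cz2 <- place_atom(cg, cd2, ce2, 1.40, 122.4, 180)
  cz3 <- place_atom(cg, cd2, ce3, 1.39, 118.7, 180)
  ch2 <- place_atom(cd2, ce2, cz2, 1.37, 117.5, 0)
  out <- rbind(CB = cb, CG = cg, CD1 = cd1, CD2 = cd2, NE1 = ne1,
               CE2 = ce2, CE3 = ce3, CZ2 = cz2, CZ3 = cz3, CH2 = ch2)
  out
}
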