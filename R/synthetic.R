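## Synthetic multi-state unfolding trajectories.
##
## A small idealised protein (one alpha-helix plus one beta-hairpin,
## optionally with side chains and a tryptophan-like bulky residue) is
## built from internal coordinates.  Partially and fully unfolded
## conformer templates are derived from it, and trajectories are generated
## by a Markov switch among templates with i.i.d. Gaussian coordinate
## jitter, so state populations, dwell times and the full hidden state
## path are known exactly.

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# segment layout of the toy fold: [coil, helix, loop, strand1, turn(2),
# strand2, coil]
.toy_layout <- function(n) {
  if (n < 12 || n > 80) stop("n_residues must be in [12, 80]")
  hl <- max(6L, min(16L, as.integer(round(0.40 * (n - 10)))))
  repeat {
    rem <- n - 2L - hl - 2L            # termini + helix + turn
    ll <- max(0L, min(4L, rem - 6L))   # loop, once strands have >= 3 each
    rem <- rem - ll
    if (rem >= 4L || hl <= 6L) break
    hl <- hl - 1L
  }
  if (rem %% 2L == 1L) { ll <- ll + 1L; rem <- rem - 1L }
  if (ll > 4L) { hl <- hl + (ll - 4L); ll <- 4L }
  sl <- rem %/% 2L
  helix <- seq(2L, 1L + hl)
  loop <- if (ll > 0) seq(max(helix) + 1L, max(helix) + ll) else integer(0)
  s1 <- seq(if (ll > 0) max(loop) + 1L else max(helix) + 1L,
            length.out = sl)
  turn <- seq(max(s1) + 1L, length.out = 2L)
  s2 <- seq(max(turn) + 1L, length.out = sl)
  stopifnot(max(s2) == n - 1L)
  list(n = n, helix = helix, loop = loop, strand1 = s1, turn = turn,
       strand2 = s2)
}

# per-residue (phi, psi) for the native toy fold; the turn torsions are a
# type-I' beta turn refined so that the two strands pair with
# Kabsch-Sander cross-strand hydrogen bonds
.TURN_PHIPSI <- matrix(c(27, 38, 140, -38), 2, 2, byrow = TRUE)
.STRAND_PHIPSI <- c(-93, 107)
.HELIX_PHIPSI <- c(-57, -47)
.LOOP_PHIPSI <- matrix(c(-70, -20, -100, 120, -80, 150, -120, 80),
                       4, 2, byrow = TRUE)
.EXTENDED_PHIPSI <- c(-150, 150)

.toy_torsions <- function(layout, unwind_prefix = 0L, unfolded = FALSE) {
  n <- layout$n
  phi <- rep(-80, n); psi <- rep(130, n)
  if (unfolded) {
    phi[] <- .EXTENDED_PHIPSI[1]; psi[] <- .EXTENDED_PHIPSI[2]
    return(cbind(phi, psi))
  }
  phi[layout$helix] <- .HELIX_PHIPSI[1]
  psi[layout$helix] <- .HELIX_PHIPSI[2]
  if (length(layout$loop)) {
    k <- ((seq_along(layout$loop) - 1) %% nrow(.LOOP_PHIPSI)) + 1
    phi[layout$loop] <- .LOOP_PHIPSI[k, 1]
    psi[layout$loop] <- .LOOP_PHIPSI[k, 2]
  }
  for (s in c(layout$strand1, layout$strand2)) {
    phi[s] <- .STRAND_PHIPSI[1]; psi[s] <- .STRAND_PHIPSI[2]
  }
  phi[layout$turn] <- .TURN_PHIPSI[, 1]
  psi[layout$turn] <- .TURN_PHIPSI[, 2]
  if (unwind_prefix > 0) {
    uw <- 1L + seq_len(min(unwind_prefix, n - 2L))
    phi[uw] <- .EXTENDED_PHIPSI[1]; psi[uw] <- .EXTENDED_PHIPSI[2]
  }
  cbind(phi, psi)
}

# build the full-atom coordinate matrix (and atom table on first call)
.build_toy_coords <- function(layout, torsions, with_sidechains,
                              trp_residue) {
  n <- layout$n
  bb <- build_backbone(torsions[, 1], torsions[, 2])
  atoms <- list(); xyz <- list()
  serial <- 0L
  for (r in seq_len(n)) {
    resname <- if (with_sidechains && r == trp_residue) "TRP"
      else if (r %in% c(layout$loop, layout$turn)) "GLY" else "ALA"
    names_r <- c("N", "CA", "C", "O")
    coords_r <- rbind(bb$N[r, ], bb$CA[r, ], bb$C[r, ], bb$O[r, ])
    if (with_sidechains && resname == "ALA") {
      names_r <- c(names_r, "CB")
      coords_r <- rbind(coords_r, place_cb(bb$N[r, ], bb$CA[r, ], bb$C[r, ]))
    } else if (with_sidechains && resname == "TRP") {
      sc <- place_trp_sidechain(bb$N[r, ], bb$CA[r, ], bb$C[r, ])
      names_r <- c(names_r, rownames(sc))
      coords_r <- rbind(coords_r, sc)
    }
    atoms[[r]] <- data.frame(
      serial = serial + seq_along(names_r), name = names_r,
      resname = resname, chain = "A", resno = r,
      element = infer_element(names_r), stringsAsFactors = FALSE)
    serial <- serial + length(names_r)
    xyz[[r]] <- coords_r
  }
  list(atoms = do.call(rbind, atoms), xyz = do.call(rbind, xyz))
}

#' Build a deterministic toy protein (helix + beta-hairpin)
#'
#' An idealised miniature fold standing in for a small alpha/beta domain:
#' one alpha-helix followed by a two-stranded antiparallel beta-hairpin,
#' built from ideal peptide internal coordinates so consecutive
#' CA-CA distances are 3.8 +/- 0.1 Angstrom.  With side chains, every
#' helix/strand residue carries a CB, loop and turn residues are glycine,
#' and one strand residue is a tryptophan-like bulky side chain whose
#' solvent exposure can be tracked during unfolding.
#'
#' @param n_residues chain length, between 12 and 80 (default 30).
#' @param with_sidechains add CB / tryptophan side-chain atoms
#'   (default TRUE).
#' @return list of class `toy_protein` with `model`
#'   ([structure_model()]), `native` (n_atoms x 3 coordinates), `layout`
#'   (residue segments), `trp_residue` (index of the bulky residue, NA
#'   without side chains).
#' @examples
#' toy <- make_toy_protein(30)
#' toy$model
#' @export
make_toy_protein <- function(n_residues = 30, with_sidechains = TRUE) {
  layout <- .toy_layout(n_residues)
  trp <- if (with_sidechains) {
    layout$strand2[ceiling(length(layout$strand2) / 2)]
  } else NA_integer_
  built <- .build_toy_coords(layout, .toy_torsions(layout),
                             with_sidechains, trp)
  structure(list(model = structure_model(built$atoms), native = built$xyz,
                 layout = layout, trp_residue = trp,
                 with_sidechains = with_sidechains),
            class = "toy_protein")
}

#' Derive intermediate and unfolded conformer templates
#'
#' The unfolded template rebuilds the whole chain with extended torsions,
#' breaking every native contact by a wide margin.  The intermediate
#' unwinds the chain from its N-terminal end residue by residue (helix
#' first, then the loop and, if needed, the outer part of the hairpin's
#' first strand; the turn-proximal hairpin stays intact) until the
#' retained fraction of native contacts is as close as possible to
#' `intermediate_fraction`; by construction
#' Rg(native) < Rg(intermediate) < Rg(unfolded).
#'
#' @param toy a [make_toy_protein()] result.
#' @param intermediate_fraction target retained native-contact fraction of
#'   the intermediate (default 0.5).
#' @param cutoff,min_sequence_separation native-contact definition used for
#'   the calibration (defaults 4.0 Angstrom, 3).
#' @return list of class `conformer_templates` with coordinate matrices
#'   `native`, `intermediate`, `unfolded`, plus `unwound` (residues
#'   unwound in the intermediate) and `intermediate_nc` (its measured
#'   native-contact fraction).
#' @export
make_templates <- function(toy, intermediate_fraction = 0.5, cutoff = 4.0,
                           min_sequence_separation = 3) {
  stopifnot(inherits(toy, "toy_protein"))
  layout <- toy$layout
  unfolded <- .build_toy_coords(layout,
                                .toy_torsions(layout, unfolded = TRUE),
                                toy$with_sidechains, toy$trp_residue)$xyz
  traj0 <- md_trajectory(toy$model, toy$native)
  native_set <- native_contacts(traj0, reference_frame = toy$native,
                                cutoff = cutoff,
                                min_sequence_separation = min_sequence_separation)
  frac_for <- function(xyz) {
    tr <- md_trajectory(toy$model, xyz)
    nc_fraction_series(tr, native_set)$values[1]
  }
  best_k <- 0L; best_frac <- 1; best_xyz <- toy$native
  for (k in seq_len(max(layout$strand1) - 1L)) {
    xyz <- .build_toy_coords(layout, .toy_torsions(layout, unwind_prefix = k),
                             toy$with_sidechains, toy$trp_residue)$xyz
    fr <- frac_for(xyz)
    if (abs(fr - intermediate_fraction) < abs(best_frac - intermediate_fraction)) {
      best_k <- k; best_frac <- fr; best_xyz <- xyz
    }
  }
  structure(list(native = toy$native, intermediate = best_xyz,
                 unfolded = unfolded,
                 unwound = 1L + seq_len(best_k),
                 intermediate_nc = best_frac),
            class = "conformer_templates")
}

#' Configuration of a synthetic multi-state trajectory
#'
#' @param n_residues toy-protein size (default 30).
#' @param n_frames number of frames (default 1500).
#' @param occupancies named probabilities over
#'   `c("native", "intermediate", "unfolded")`; must sum to 1.
#' @param jitter_sigma Gaussian coordinate noise SD per axis, Angstrom
#'   (default 0.3, small against the 4-Angstrom contact cutoff so state
#'   identity dominates Nc).
#' @param dwell mean frames between state-switch attempts (default 5);
#'   the realised mean dwell in state i is `dwell / (1 - p_i)`.
#' @param temperature temperature label in K (metadata).
#' @param seed master seed; every draw derives from it.
#' @param with_sidechains forwarde to [make_toy_protein()].
#' @param intermediate_fraction forwarded to [make_templates()].
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_residues = 30, n_frames = 1500,
                             occupancies = c(native = 1),
                             jitter_sigma = 0.3, dwell = 5,
                             temperature = 300, seed = 1,
                             with_sidechains = TRUE,
                             intermediate_fraction = 0.5) {
  occupancies <- unlist(occupancies)
  bad <- setdiff(names(occupancies), c("native", "intermediate", "unfolded"))
  if (length(bad)) stop("unknown template(s): ", paste(bad, collapse = ", "))
  if (any(occupancies < 0) || abs(sum(occupancies) - 1) > 1e-8) {
    stop("occupancies must be non-negative and sum to 1")
  }
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  if (dwell < 1) stop("dwell must be >= 1")
  structure(list(n_residues = n_residues, n_frames = n_frames,
                 occupancies = occupancies, jitter_sigma = jitter_sigma,
                 dwell = dwell, temperature = temperature, seed = seed,
                 with_sidechains = with_sidechains,
                 intermediate_fraction = intermediate_fraction),
            class = "synthetic_config")
}

#' Simulate a Markov-switching multi-state trajectory
#'
#' The hidden conformational state follows a Markov chain whose stationary
#' distribution equals the configured occupancies (transition
#' `i -> j != i` with probability `p_j / dwell`, which satisfies detailed
#' balance); each frame is the current state's template plus i.i.d.
#' Gaussian jitter.  Output is bit-identical for a fixed seed and can be
#' written as a multi-model PDB with [write_multimodel_pdb()].
#'
#' @param config a [synthetic_config()].
#' @param toy,templates optionally a pre-built [make_toy_protein()] /
#'   [make_templates()] pair (rebuilt from `config` when NULL).
#' @return an [md_trajectory()] with attributes `state_path` (per-frame
#'   hidden state) and `config`.
#' @export
simulate_trajectory <- function(config, toy = NULL, templates = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(toy)) {
    toy <- make_toy_protein(config$n_residues, config$with_sidechains)
  }
  if (is.null(templates)) {
    templates <- make_templates(toy, config$intermediate_fraction)
  }
  occ <- config$occupancies
  states <- names(occ)
  tpl <- templates[states]
  if (any(vapply(tpl, is.null, logical(1)))) {
    stop("occupancy refers to a template that was not built")
  }
  n_atoms <- nrow(toy$native)
  nf <- config$n_frames
  path <- character(nf)
  coords <- .with_seed(config$seed, {
    # stationary start, then Markov switching
    s <- sample(states, 1, prob = occ)
    path[1] <- s
    if (nf > 1) {
      u <- runif(nf - 1)
      for (f in 2:nf) {
        p_leave <- (1 - occ[[s]]) / config$dwell
        if (u[f - 1] < p_leave) {
          others <- setdiff(states, s)
          w <- occ[others]
          s <- if (length(others) == 1) others else
            sample(others, 1, prob = w)
        }
        path[f] <- s
      }
    }
    arr <- array(rnorm(n_atoms * 3 * nf, sd = config$jitter_sigma),
                 dim = c(n_atoms, 3, nf))
    for (st in unique(path)) {
      idx <- which(path == st)
      arr[, , idx] <- arr[, , idx, drop = FALSE] +
        array(tpl[[st]], dim = c(n_atoms, 3, length(idx)))
    }
    arr
  })
  traj <- md_trajectory(toy$model, coords,
                        times = (seq_len(nf) - 1) * 10,
                        temperature = config$temperature)
  attr(traj, "state_path") <- path
  attr(traj, "config") <- config
  attr(traj, "native_template") <- templates$native
  traj
}

#' Write a trajectory's hidden-state ground truth as CSV
#'
#' @param traj a [simulate_trajectory()] result.
#' @param path output CSV (`frame`, `time_ps`, `state`).
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(traj, path) {
  sp <- attr(traj, "state_path")
  if (is.null(sp)) stop("trajectory carries no hidden-state ground truth")
  write.csv(data.frame(frame = seq_along(sp), time_ps = traj$times,
                       state = sp),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# default temperature -> occupancy schedule: occupancy mass moves
# native -> intermediate -> unfolded as temperature rises
.default_schedule <- function() {
  list(`300` = c(native = 0.96, intermediate = 0.03, unfolded = 0.01),
       `350` = c(native = 0.80, intermediate = 0.15, unfolded = 0.05),
       `400` = c(native = 0.45, intermediate = 0.40, unfolded = 0.15),
       `450` = c(native = 0.10, intermediate = 0.40, unfolded = 0.50),
       `500` = c(native = 0.02, intermediate = 0.08, unfolded = 0.90))
}

#' Simulate a thermal ladder of trajectories
#'
#' One trajectory per temperature, with state occupancies following an
#' unfolding schedule (the default moves occupancy mass native ->
#' intermediate -> unfolded as the temperature rises, mimicking
#' accelerated thermal unfolding at 300-500 K).  All trajectories share
#' one topology and native template; per-temperature seeds derive from
#' the base config's master seed.
#'
#' @param config a [synthetic_config()]; its `occupancies` field is
#'   overridden per temperature.
#' @param schedule named list mapping temperature (K, as name) to
#'   occupancy vectors; default [.default_schedule()] at 300-500 K.
#' @return named list of [md_trajectory()] (names like `"300K"`).
#' @export
thermal_series <- function(config = synthetic_config(),
                           schedule = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(schedule)) schedule <- .default_schedule()
  toy <- make_toy_protein(config$n_residues, config$with_sidechains)
  templates <- make_templates(toy, config$intermediate_fraction)
  temps <- as.numeric(names(schedule))
  out <- vector("list", length(schedule))
  for (i in seq_along(schedule)) {
    ci <- config
    ci$occupancies <- schedule[[i]]
    ci$temperature <- temps[i]
    ci$seed <- config$seed + 1000L * i
    cl <- class(ci)
    ci <- synthetic_config(n_residues = ci$n_residues, n_frames = ci$n_frames,
                           occupancies = ci$occupancies,
                           jitter_sigma = ci$jitter_sigma, dwell = ci$dwell,
                           temperature = ci$temperature, seed = ci$seed,
                           with_sidechains = ci$with_sidechains,
                           intermediate_fraction = ci$intermediate_fraction)
    out[[i]] <- simulate_trajectory(ci, toy = toy, templates = templates)
  }
  names(out) <- paste0(temps, "K")
  out
}
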