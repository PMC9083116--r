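## Multi-model PDB ingestion and atom selection.
##
## Trajectories are represented as a fixed topology (`structure_model`) plus
## an n_atoms x 3 x n_frames coordinate array in Angstrom (`md_trajectory`).
## The first MODEL of a file defines the topology; every later MODEL must
## present the same atoms in the same order.

# per-element van der Waals radii (A) and atomic masses (amu); a single
# documented table applied uniformly
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.VDW_DEFAULT <- 1.70
.MASSES <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008,
             P = 30.974)
.MASS_DEFAULT <- 12.011

.BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Infer the chemical element from a PDB atom name
#'
#' Used when the element column (77-78) is absent.  Leading digits are
#' stripped; a name then starting with `H` is hydrogen, otherwise the first
#' letter is taken as the element symbol.
#'
#' @param name character vector of atom names (e.g. `"CA"`, `"1HB"`, `"OXT"`).
#' @return character vector of element symbols.
#' @keywords internal
infer_element <- function(name) {
  stripped <- toupper(sub("^[0-9]+", "", trimws(name)))
  vapply(stripped, function(s) {
    if (nchar(s) == 0L) return("C")
    substr(s, 1L, 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a structure model from an atom table
#'
#' A `structure_model` is the fixed topology shared by every frame of a
#' trajectory: one row per atom with element, residue assignment,
#' backbone/side-chain flags, van der Waals radius and mass.  Residues must
#' appear as contiguous blocks of atoms; internal residue indices are
#' renumbered 1..n_residues in order of first appearance while the file
#' numbering (`resno`) is preserved for reporting.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resno`,
#'   `resname`, `chain`, and optionally `element`.
#' @return object of class `structure_model`: list with `atoms` (augmented
#'   table), `n_residues`, and `res_atoms` (list of atom index vectors per
#'   residue).
#' @export
structure_model <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  need <- c("serial", "name", "resno", "resname", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  atoms$name <- trimws(atoms$name)
  if (is.null(atoms$element) || all(is.na(atoms$element)) ) {
    atoms$element <- infer_element(atoms$name)
  } else {
    atoms$element <- toupper(trimws(atoms$element))
    blank <- is.na(atoms$element) | atoms$element == ""
    atoms$element[blank] <- infer_element(atoms$name[blank])
  }

  key <- paste(atoms$chain, atoms$resno)
  new_block <- c(TRUE, key[-1] != key[-length(key)])
  ridx <- cumsum(new_block)
  # contiguity: each (chain, resno) pair must form exactly one block
  if (anyDuplicated(key[new_block])) {
    stop("residues are not contiguous along the atom sequence")
  }
  atoms$res_index <- ridx

  atoms$radius <- unname(.VDW_RADII[atoms$element])
  atoms$radius[is.na(atoms$radius)] <- .VDW_DEFAULT
  atoms$mass <- unname(.MASSES[atoms$element])
  atoms$mass[is.na(atoms$mass)] <- .MASS_DEFAULT
  atoms$is_heavy <- atoms$element != "H"
  atoms$is_backbone <- atoms$name %in% .BACKBONE_NAMES
  atoms$is_sidechain <- atoms$is_heavy & !atoms$is_backbone

  structure(list(atoms = atoms,
                 n_residues = max(ridx),
                 res_atoms = split(seq_len(nrow(atoms)), ridx)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms (%d heavy), %d residues\n",
              nrow(x$atoms), sum(x$atoms$is_heavy), x$n_residues))
  invisible(x)
}

#' Construct a trajectory over a fixed topology
#'
#' @param model a [structure_model()].
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom), or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param times per-frame times in ps, strictly increasing.  Defaults to
#'   `0, 10, 20, ...` ps (a common trajectory save interval).
#' @param temperature temperature label in K (metadata only).
#' @return object of class `md_trajectory`: list with `model`, `coords`,
#'   `times`, `temperature`.
#' @export
md_trajectory <- function(model, coords, times = NULL, temperature = NA_real_) {
  stopifnot(inherits(model, "structure_model"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_atoms <- nrow(model$atoms)
  if (dim(coords)[1] != n_atoms) {
    stop(sprintf("coordinate array has %d atoms but model has %d",
                 dim(coords)[1], n_atoms))
  }
  nf <- dim(coords)[3]
  if (is.null(times)) times <- (seq_len(nf) - 1) * 10
  if (length(times) != nf) stop("times length must equal number of frames")
  if (nf > 1 && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(model = model, coords = coords, times = as.numeric(times),
                 temperature = temperature),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames, %d atoms, %d residues%s\n",
              n_frames(x), nrow(x$model$atoms), x$model$n_residues,
              if (is.na(x$temperature)) "" else sprintf(", T = %g K", x$temperature)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  x <- traj$coords[, , i, drop = FALSE]
  dim(x) <- dim(x)[1:2]
  x
}

.parse_atom_line <- function(line, lineno) {
  x <- suppressWarnings(as.numeric(substr(line, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(line, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(line, 47, 54)))
  if (anyNA(c(x, y, z))) {
    stop(sprintf("unparseable ATOM record at line %d: %s", lineno,
                 substr(line, 1, 54)))
  }
  serial <- suppressWarnings(as.integer(substr(line, 7, 11)))
  resno <- suppressWarnings(as.integer(substr(line, 23, 26)))
  if (is.na(resno)) {
    stop(sprintf("unparseable residue number at line %d", lineno))
  }
  list(serial = if (is.na(serial)) 0L else serial,
       name = trimws(substr(line, 13, 16)),
       resname = trimws(substr(line, 18, 20)),
       chain = trimws(substr(line, 22, 22)),
       resno = resno,
       element = trimws(substr(line, 77, 78)),
       x = x, y = y, z = z)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Sequential `MODEL`/`ENDMDL` blocks over a fixed topology are read as
#' frames; a file without `MODEL` records is a single-frame trajectory.
#' The topology (atom names, residues, elements, radii, masses) is built
#' from the first model; later models must carry the same number of atoms
#' in the same order.
#'
#' @param path PDB file path.
#' @param dt frame spacing in ps used to synthesise frame times (PDB files
#'   carry none); default 10 ps.
#' @param temperature temperature label in K attached to the trajectory.
#' @return an [md_trajectory()] (its `$model` is the topology).
#' @examples
#' pdb <- system.file("extdata", "mini.pdb", package = "mdunfold")
#' if (nzchar(pdb)) read_multimodel_pdb(pdb)
#' @export
read_multimodel_pdb <- function(path, dt = 10, temperature = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(rec, "MODEL")
  is_end <- startsWith(rec, "ENDMDL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # assign a model ordinal to every line
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  model_id[model_id == 0L] <- 1L
  # drop atom lines after ENDMDL but before the next MODEL (there are none
  # in well-formed files; cheap guard)
  atom_idx <- which(is_atom)
  mids <- model_id[atom_idx]
  models <- split(atom_idx, mids)

  first <- lapply(models[[1]], function(i) .parse_atom_line(lines[i], i))
  atoms <- data.frame(
    serial = vapply(first, `[[`, integer(1), "serial"),
    name = vapply(first, `[[`, character(1), "name"),
    resname = vapply(first, `[[`, character(1), "resname"),
    chain = vapply(first, `[[`, character(1), "chain"),
    resno = vapply(first, `[[`, integer(1), "resno"),
    element = vapply(first, `[[`, character(1), "element"),
    stringsAsFactors = FALSE
  )
  model <- structure_model(atoms)
  n_atoms <- nrow(atoms)

  nf <- length(models)
  coords <- array(NA_real_, dim = c(n_atoms, 3L, nf))
  model_labels <- names(models)
  for (f in seq_len(nf)) {
    idx <- models[[f]]
    if (length(idx) != n_atoms) {
      stop(sprintf(
        "model %s has %d atoms but the first model has %d: trajectory topology must be fixed",
        model_labels[f], length(idx), n_atoms))
    }
    parsed <- lapply(idx, function(i) .parse_atom_line(lines[i], i))
    coords[, 1, f] <- vapply(parsed, `[[`, numeric(1), "x")
    coords[, 2, f] <- vapply(parsed, `[[`, numeric(1), "y")
    coords[, 3, f] <- vapply(parsed, `[[`, numeric(1), "z")
  }
  md_trajectory(model, coords, times = (seq_len(nf) - 1) * dt,
                temperature = temperature)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj an [md_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  a <- traj$model$atoms
  nf <- n_frames(traj)
  name_fmt <- ifelse(nchar(a$name) < 4 & nchar(a$element) == 1,
                     sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f, drop = TRUE]
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a$serial, name_fmt, a$resname, a$chain, a$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms of a structure model
#'
#' @param model a [structure_model()].
#' @param selection one of `"calpha"`, `"heavy"`, `"backbone"`,
#'   `"sidechain"`, `"all"`.  `"backbone"` means heavy backbone atoms
#'   (N, CA, C, O); `"sidechain"` means the heavy side-chain atoms of the
#'   residue given by `residue`.
#' @param residue internal residue index (1-based), required for
#'   `"sidechain"`.
#' @return strictly increasing integer vector of atom indices.  A glycine
#'   side-chain request returns an empty set with a warning.
#' @export
select_atoms <- function(model,
                         selection = c("calpha", "heavy", "backbone",
                                       "sidechain", "all"),
                         residue = NULL) {
  selection <- match.arg(selection)
  a <- model$atoms
  idx <- switch(selection,
    all = seq_len(nrow(a)),
    heavy = which(a$is_heavy),
    backbone = which(a$is_backbone & a$is_heavy),
    calpha = which(a$name == "CA" & a$is_heavy),
    sidechain = {
      if (is.null(residue)) stop("selection 'sidechain' requires `residue`")
      if (residue < 1 || residue > model$n_residues) {
        stop("residue index out of range: ", residue)
      }
      out <- which(a$res_index == residue & a$is_sidechain)
      if (length(out) == 0L) {
        warning(sprintf("residue %d (%s) has no heavy side-chain atoms",
                        residue, a$resname[match(residue, a$res_index)]))
      }
      out
    })
  as.integer(idx)
}
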