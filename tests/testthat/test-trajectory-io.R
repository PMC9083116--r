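# Multi-model PDB ingestion, atom selection and tabular round-trips.

write_pdb_text <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

atom_line <- function(serial, name, resname, resno, x, y, z, element) {
  sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, resno, x, y, z, element)
}

test_that("a single-model PDB ingests as a one-frame trajectory", {
  f <- write_pdb_text(c(
    atom_line(1, "N", "ALA", 1, 0, 0, 0, "N"),
    atom_line(2, "CA", "ALA", 1, 1.458, 0, 0, "C"),
    atom_line(3, "C", "ALA", 1, 2.0, 1.4, 0, "C"),
    atom_line(4, "O", "ALA", 1, 2.0, 2.6, 0, "O"),
    atom_line(5, "CB", "ALA", 1, 1.8, -1.0, 1.0, "C"),
    "END"))
  tr <- read_multimodel_pdb(f)
  expect_equal(n_frames(tr), 1L)
  expect_equal(nrow(tr$model$atoms), 5L)
  expect_equal(tr$model$n_residues, 1L)
  expect_equal(frame_coords(tr, 1)[2, ], c(1.458, 0, 0))
  expect_true(all(tr$model$atoms$radius > 0))
  expect_true(all(tr$model$atoms$mass > 0))
})

test_that("identical models give identical frames (zero RMSD downstream)", {
  block <- c(atom_line(1, "CA", "ALA", 1, 0, 0, 0, "C"),
             atom_line(2, "CA", "ALA", 2, 3.8, 0, 0, "C"),
             atom_line(3, "CA", "ALA", 3, 7.6, 0.5, 0, "C"))
  f <- write_pdb_text(c("MODEL        1", block, "ENDMDL",
                        "MODEL        2", block, "ENDMDL",
                        "MODEL        3", block, "ENDMDL", "END"))
  tr <- read_multimodel_pdb(f)
  expect_equal(n_frames(tr), 3L)
  s <- rmsd_series(tr, selection = select_atoms(tr$model, "all"))
  expect_equal(s$values, c(0, 0, 0), tolerance = 1e-12)
})

test_that("a model with a dropped atom is rejected, naming the model", {
  f <- write_pdb_text(c(
    "MODEL        1",
    atom_line(1, "CA", "ALA", 1, 0, 0, 0, "C"),
    atom_line(2, "CA", "ALA", 2, 3.8, 0, 0, "C"),
    "ENDMDL",
    "MODEL        2",
    atom_line(1, "CA", "ALA", 1, 0, 0, 0, "C"),
    "ENDMDL", "END"))
  expect_error(read_multimodel_pdb(f), "model 2")
})

test_that("an unparseable ATOM record reports its line number", {
  f <- write_pdb_text(c(
    atom_line(1, "CA", "ALA", 1, 0, 0, 0, "C"),
    "ATOM      2  CA  ALA A   2        garbage coordinates            C"))
  expect_error(read_multimodel_pdb(f), "line 2")
})

test_that("ingestion is a fixed point under write/read round-trips", {
  toy <- make_toy_protein(14)
  tr <- md_trajectory(toy$model, toy$native)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(tr, f1)
  tr1 <- read_multimodel_pdb(f1)
  write_multimodel_pdb(tr1, f2)
  tr2 <- read_multimodel_pdb(f2)
  expect_identical(tr1$coords, tr2$coords)
  expect_identical(tr1$model$atoms$name, tr2$model$atoms$name)
  # and the first read is already within PDB print precision of the source
  expect_lt(max(abs(tr1$coords - tr$coords)), 5e-4)
})

test_that("atom selections honour their contracts", {
  toy <- make_toy_protein(30)
  m <- toy$model
  ca <- select_atoms(m, "calpha")
  expect_length(ca, 30L)
  expect_true(all(diff(ca) > 0))
  expect_true(all(m$atoms$name[ca] == "CA"))

  sc <- select_atoms(m, "sidechain", residue = toy$trp_residue)
  expect_length(sc, 10L)  # tryptophan: CB..CH2 heavy atoms

  gly <- which(m$atoms$resname == "GLY")[1]
  expect_warning(
    empty <- select_atoms(m, "sidechain", residue = m$atoms$res_index[gly]),
    "side-chain")
  expect_length(empty, 0L)

  bb <- select_atoms(m, "backbone")
  expect_setequal(unique(m$atoms$name[bb]), c("N", "CA", "C", "O"))
  expect_error(select_atoms(m, "sidechain", residue = 99), "out of range")
})

test_that("selection is independent of atom serial numbering", {
  toy <- make_toy_protein(20)
  a2 <- toy$model$atoms[, c("serial", "name", "resname", "chain", "resno",
                            "element")]
  a2$serial <- rev(seq_len(nrow(a2))) * 7L
  m2 <- structure_model(a2)
  for (sel in c("calpha", "heavy", "backbone", "all")) {
    expect_identical(select_atoms(toy$model, sel), select_atoms(m2, sel))
  }
})

test_that("hydrogens are recognised and excluded from heavy selections", {
  at <- data.frame(serial = 1:4, name = c("N", "H", "CA", "1HB"),
                   resname = "ALA", chain = "A", resno = 1,
                   element = c("N", "", "C", ""))
  m <- structure_model(at)
  expect_identical(m$atoms$element, c("N", "H", "C", "H"))
  expect_identical(select_atoms(m, "heavy"), c(1L, 3L))
})

test_that("series, grid and matrix files round-trip exactly", {
  s <- op_series("rg", "A", c(pi, exp(1), sqrt(2)) * 10, c(0, 10, 20), 300)
  f <- tempfile(fileext = ".csv")
  write_series_csv(s, f)
  s2 <- read_series_csv(f)
  expect_identical(s2$values, s$values)
  expect_identical(s2$times, s$times)
  expect_identical(s2$units, "A")

  x <- op_series("x", "", rep(c(0, 1, 2), c(50, 30, 20)), 1:100)
  y <- op_series("y", "", rep(c(0, 2, 1), c(50, 30, 20)), 1:100)
  g <- fel_2d(x, y, n_bins = c(5, 5), temperature = 300)
  fg <- tempfile(fileext = ".txt")
  write_fel_grid(g, fg)
  g2 <- read_fel_grid(fg)
  expect_identical(g2$F, g$F)
  expect_identical(g2$mask, g$mask)
  expect_identical(g2$x_edges, g$x_edges)
  expect_identical(g2$rt, g$rt)

  toy <- make_toy_protein(16)
  cfg <- synthetic_config(n_residues = 16, n_frames = 40, seed = 3)
  trj <- simulate_trajectory(cfg)
  d <- dccm_matrix(trj, window = c(1, 40))
  fd <- tempfile(fileext = ".csv")
  write_dccm_csv(d, fd)
  d2 <- read_dccm_csv(fd)
  expect_identical(d2$values, d$values)
  expect_true(isSymmetric(d2$values))
})
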