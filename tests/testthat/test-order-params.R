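# Radius of gyration, native contacts, Nc fraction and H-bond counts.

two_atom_model <- function() {
  structure_model(data.frame(
    serial = 1:2, name = c("CA", "CA"), resname = "ALA", chain = "A",
    resno = 1:2, element = "C", stringsAsFactors = FALSE))
}

test_that("radius of gyration matches closed forms", {
  m <- two_atom_model()
  tr <- md_trajectory(m, rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration_series(tr, mass_weighted = FALSE)$values,
               1.0, tolerance = 1e-12)
  tr0 <- md_trajectory(m, rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(radius_of_gyration_series(tr0)$values, 0, tolerance = 1e-12)

  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  m8 <- ca_only_model(8)
  tr8 <- md_trajectory(m8, cube)
  expect_equal(radius_of_gyration_series(tr8, mass_weighted = FALSE)$values,
               sqrt(0.75), tolerance = 1e-12)
})

test_that("Rg is invariant under rigid motion without alignment", {
  toy <- make_toy_protein(18)
  th <- 1.1
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(toy$native %*% t(Rz), 2, c(30, -12, 7), `+`)
  tr <- md_trajectory(toy$model,
                      array(c(toy$native, moved),
                            dim = c(nrow(toy$native), 3, 2)))
  rg <- radius_of_gyration_series(tr)
  expect_equal(rg$values[1], rg$values[2], tolerance = 1e-10)
})

test_that("the 4-Angstrom contact cutoff is honoured at 3.9 vs 4.1", {
  # two far-separated residue blocks plus spacers to satisfy |dres| >= 3
  mk <- function(gap) {
    m <- ca_only_model(5)
    xyz <- rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0), c(300, 0, 0),
                 c(gap, 0, 0))  # residue 5 near residue 1
    md_trajectory(m, xyz)
  }
  nc39 <- native_contacts(mk(3.9), min_sequence_separation = 3)
  expect_equal(nc39$n_pairs, 1L)
  expect_identical(unname(nc39$pairs[1, ]), c(1L, 5L))
  expect_error(native_contacts(mk(4.1), min_sequence_separation = 3),
               "no native contacts")
})

test_that("contact pairs are stored once with i < j", {
  toy <- make_toy_protein(30)
  nc <- native_contacts(md_trajectory(toy$model, toy$native))
  expect_true(all(nc$pairs[, 1] < nc$pairs[, 2]))
  expect_false(anyDuplicated(paste(nc$pairs[, 1], nc$pairs[, 2])) > 0)
  res <- toy$model$atoms$res_index
  expect_true(all(abs(res[nc$pairs[, 1]] - res[nc$pairs[, 2]]) >= 3))
})

test_that("the fully extended template has no native contacts", {
  toy <- make_toy_protein(24)
  tpl <- make_templates(toy)
  expect_error(
    native_contacts(md_trajectory(toy$model, tpl$unfolded),
                    min_sequence_separation = 3),
    "no native contacts")
})

test_that("nc fraction is 1 on the reference and counts broken pairs", {
  # five disjoint contact pairs: residues (4k+1, 4k+4), members 3 A apart
  n <- 20
  m <- ca_only_model(n)
  xyz <- matrix(0, n, 3)
  for (k in 0:4) {
    base <- c(0, 0, 60 * k)
    xyz[4 * k + 1, ] <- base
    xyz[4 * k + 2, ] <- base + c(20, 0, 0)
    xyz[4 * k + 3, ] <- base + c(40, 0, 0)
    xyz[4 * k + 4, ] <- base + c(3, 0, 0)
  }
  tr <- md_trajectory(m, xyz)
  nc <- native_contacts(tr, min_sequence_separation = 3)
  expect_equal(nc$n_pairs, 5L)
  expect_equal(nc_fraction_series(tr, nc)$values, 1.0)

  # stretch two of the five pairs beyond the cutoff -> 0.6
  broken <- xyz
  broken[4, 1] <- 10; broken[8, 1] <- 10
  tr2 <- md_trajectory(m, array(c(xyz, broken), dim = c(n, 3, 2)))
  expect_equal(nc_fraction_series(tr2, nc)$values, c(1.0, 0.6))

  # every pair stretched -> 0
  allgone <- xyz; allgone[4 * (0:4) + 4, 1] <- 10
  tr3 <- md_trajectory(m, allgone)
  expect_equal(nc_fraction_series(tr3, nc)$values, 0.0)
})

test_that("nc series equals a brute-force recomputation on synthetic data", {
  cfg <- synthetic_config(n_frames = 200,
                          occupancies = c(native = 0.5, intermediate = 0.3,
                                          unfolded = 0.2), seed = 21)
  trj <- simulate_trajectory(cfg)
  toy <- make_toy_protein(30)
  nc <- native_contacts(md_trajectory(toy$model, toy$native),
                        reference_frame = toy$native)
  expect_equal(nc_fraction_series(trj, nc)$values, brute_force_nc(trj, nc),
               tolerance = 1e-12)
})

test_that("hydrogen-bond counting follows the geometric criterion", {
  # all N...O far apart -> 0
  n <- 6
  bb <- mdunfold:::build_backbone(rep(-150, n), rep(150, n))
  fx <- backbone_model(bb, n, with_cb = FALSE)
  far <- hbond_count_series(md_trajectory(fx$model, fx$xyz))
  expect_equal(far$values, 0)

  # constructed single N-H...O at 2.9 A, 180 degrees between residues
  # two apart (a spacer residue sits far away in between)
  at <- data.frame(
    serial = 1:8,
    name = c("N", "CA", "C", "O", "CA", "N", "CA", "H"),
    resname = "ALA", chain = "A",
    resno = c(1, 1, 1, 1, 2, 3, 3, 3),
    element = c("N", "C", "C", "O", "C", "N", "C", "H"))
  xyz <- rbind(c(8, 0, 0), c(6.5, 0, 0), c(1.2, 1.2, 0), c(0, 0, 0),
               c(50, 50, 50),
               c(0, 0, 2.9), c(1.4, 0, 3.4), c(0, 0, 1.9))
  tr <- md_trajectory(structure_model(at), xyz)
  expect_equal(hbond_count_series(tr)$values, 1)

  # ideal 12-residue helix: the 8 interior i -> i+4 bonds
  hx <- helix_fixture(12, with_cb = FALSE)
  expect_equal(hbond_count_series(hx)$values, 8)
})

test_that("helix hydrogen bonds are the i to i+4 pairs by brute force", {
  n <- 12
  bb <- mdunfold:::build_backbone(rep(-57, n), rep(-47, n))
  found <- 0L
  for (i in 1:(n - 4)) {
    dNO <- sqrt(sum((bb$N[i + 4, ] - bb$O[i, ])^2))
    # reconstructed H of residue i+4
    v <- bb$C[i + 3, ] - bb$O[i + 3, ]
    h <- bb$N[i + 4, ] + 1.01 * v / sqrt(sum(v^2))
    v1 <- bb$N[i + 4, ] - h; v2 <- bb$O[i, ] - h
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    if (dNO <= 3.5 && ang >= 120) found <- found + 1L
  }
  expect_equal(found, 8L)
})
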