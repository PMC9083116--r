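# Toy-protein builder, conformer templates and the Markov-switching
# trajectory generator.

test_that("the toy protein is deterministic with ideal CA spacing", {
  t1 <- make_toy_protein(30)
  t2 <- make_toy_protein(30)
  expect_identical(t1$native, t2$native)
  ca <- t1$native[select_atoms(t1$model, "calpha"), ]
  spacing <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(spacing - 3.8) <= 0.1))
  expect_error(make_toy_protein(8), "12")
  expect_error(make_toy_protein(120), "80")
})

test_that("the native fold carries helix, strands and long-range contacts", {
  toy <- make_toy_protein(30)
  tr <- md_trajectory(toy$model, toy$native)
  codes <- assign_frame(tr)
  expect_true(all(codes[toy$layout$helix[2:6]] == "H"))
  expect_gte(sum(codes == "E"), 8)
  nc <- native_contacts(tr)
  expect_gt(nc$n_pairs, 0)
  res <- toy$model$atoms$res_index
  expect_true(any(abs(res[nc$pairs[, 1]] - res[nc$pairs[, 2]]) > 8))
})

test_that("templates satisfy their construction invariants", {
  toy <- make_toy_protein(30)
  tpl <- make_templates(toy)
  tr0 <- md_trajectory(toy$model, toy$native)
  nc <- native_contacts(tr0)

  # native template reproduces all of its own contacts
  expect_equal(nc_fraction_series(tr0, nc)$values, 1.0)

  # unfolded template breaks every contact with margin over jitter
  h <- select_atoms(toy$model, "heavy")
  res <- toy$model$atoms$res_index[h]
  d <- as.matrix(dist(tpl$unfolded[h, ]))
  sep <- abs(outer(res, res, `-`))
  expect_gt(min(d[sep >= 3]), 4 + 6 * 0.3)
  expect_equal(
    nc_fraction_series(md_trajectory(toy$model, tpl$unfolded), nc)$values, 0)

  # intermediate retains about half the native contacts
  expect_gte(tpl$intermediate_nc, 0.4)
  expect_lte(tpl$intermediate_nc, 0.6)
  fr <- nc_fraction_series(md_trajectory(toy$model, tpl$intermediate),
                           nc)$values
  expect_equal(fr, tpl$intermediate_nc)

  # compactness ordering
  rg_of <- function(x) {
    radius_of_gyration_series(md_trajectory(toy$model, x))$values
  }
  expect_lt(rg_of(tpl$native), rg_of(tpl$intermediate))
  expect_lt(rg_of(tpl$intermediate), rg_of(tpl$unfolded))
})

test_that("a fixed seed reproduces trajectories bit for bit", {
  cfg <- synthetic_config(n_frames = 50, seed = 123,
                          occupancies = c(native = 0.5, unfolded = 0.5))
  a <- simulate_trajectory(cfg)
  b <- simulate_trajectory(cfg)
  expect_identical(a$coords, b$coords)
  expect_identical(attr(a, "state_path"), attr(b, "state_path"))
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulate_trajectory(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("config validation rejects bad occupancies", {
  expect_error(synthetic_config(occupancies = c(molten = 1)), "unknown")
  expect_error(synthetic_config(occupancies = c(native = 0.7)), "sum to 1")
  expect_error(synthetic_config(occupancies = c(native = 1), dwell = 0.5),
               "dwell")
  expect_error(synthetic_config(occupancies = c(native = 1),
                                jitter_sigma = -1), "jitter")
})

test_that("pure-state trajectories sit at their template's Nc level", {
  toy <- make_toy_protein(30)
  nc <- native_contacts(md_trajectory(toy$model, toy$native),
                        reference_frame = toy$native)

  cfg_n <- synthetic_config(n_frames = 300, seed = 7,
                            occupancies = c(native = 1))
  s_n <- nc_fraction_series(simulate_trajectory(cfg_n), nc)
  expect_gt(mean(s_n$values), 0.8)

  cfg_u <- synthetic_config(n_frames = 300, seed = 7,
                            occupancies = c(unfolded = 1))
  s_u <- nc_fraction_series(simulate_trajectory(cfg_u), nc)
  expect_true(all(s_u$values < 0.01))
  expect_gt(mean(s_n$values) - mean(s_u$values), 0.75)
})

test_that("state frequencies recover the configured occupancies", {
  cfg <- synthetic_config(n_frames = 20000, seed = 37, dwell = 5,
                          with_sidechains = FALSE,
                          occupancies = c(native = 0.7, unfolded = 0.3))
  trj <- simulate_trajectory(cfg)
  path <- attr(trj, "state_path")
  p_hat <- mean(path == "native")
  # binomial bound inflated for Markov autocorrelation:
  # var ~ p(1-p)/n * (1+rho)/(1-rho) with stay probability rho
  rho <- 1 - (1 - 0.7) / 5
  se <- sqrt(0.7 * 0.3 / 20000 * (1 + rho) / (1 - rho))
  expect_lt(abs(p_hat - 0.7), 3 * se + 0.01)
})

test_that("ground truth exports alongside the trajectory", {
  cfg <- synthetic_config(n_frames = 25, seed = 3,
                          occupancies = c(native = 0.5, intermediate = 0.5))
  trj <- simulate_trajectory(cfg)
  f <- tempfile(fileext = ".csv")
  write_ground_truth_csv(trj, f)
  gt <- read.csv(f)
  expect_equal(nrow(gt), 25L)
  expect_identical(gt$state, attr(trj, "state_path"))
})

test_that("the thermal ladder unfolds monotonically with temperature", {
  cfg <- synthetic_config(n_frames = 800, seed = 11)
  ladder <- thermal_series(cfg)
  expect_named(ladder, c("300K", "350K", "400K", "450K", "500K"))
  toy <- make_toy_protein(30)
  nc <- native_contacts(md_trajectory(toy$model, toy$native),
                        reference_frame = toy$native)
  mean_nc <- vapply(ladder, function(tr) {
    mean(nc_fraction_series(tr, nc)$values)
  }, numeric(1))
  mean_rg <- vapply(ladder, function(tr) {
    mean(radius_of_gyration_series(tr)$values)
  }, numeric(1))
  expect_true(all(diff(mean_nc) < 0))
  expect_true(all(diff(mean_rg) > 0))

  # reproducible ladder
  ladder2 <- thermal_series(cfg)
  expect_identical(ladder[["450K"]]$coords, ladder2[["450K"]]$coords)
})

test_that("generated trajectories are valid multi-model PDB round-trips", {
  cfg <- synthetic_config(n_residues = 16, n_frames = 5, seed = 2,
                          occupancies = c(native = 0.5, unfolded = 0.5))
  trj <- simulate_trajectory(cfg)
  f <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(trj, f)
  back <- read_multimodel_pdb(f)
  expect_equal(n_frames(back), 5L)
  expect_lt(max(abs(back$coords - trj$coords)), 5e-4)
  expect_identical(back$model$atoms$name, trj$model$atoms$name)
})
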