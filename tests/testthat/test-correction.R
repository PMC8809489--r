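mono <- function(mult, d_base, d_target) {
  data.frame(monomer_id = paste0("m", seq_along(mult)), multiplicity = mult,
             e_base = d_base, e_target = d_target)
}

test_that("the monomer correction reproduces hand arithmetic", {
  # zero correction is the identity on energies
  r0 <- apply_monomer_correction(
    energy_record("x", -400, 4, mono(4, 1.3, 1.3)))
  expect_equal(r0$e_corrected_cell, -400)
  expect_equal(r0$e_per_molecule, -100)

  # Z = 4, Z' = 1, delta = +2.5 per monomer
  r1 <- apply_monomer_correction(
    energy_record("x", -400, 4, mono(4, 0, 2.5)))
  expect_equal(r1$e_corrected_cell, -390)
  expect_equal(r1$e_per_molecule, -97.5)

  # Z' = 2: multiplicities 2 and 2 with deltas +1 and -3 -> cell shift -4
  r2 <- apply_monomer_correction(
    energy_record("x", -400, 4, mono(c(2, 2), c(0, 0), c(1, -3))))
  expect_equal(r2$e_corrected_cell, -404)
})

test_that("multiplicity bookkeeping and the re-application guard hold", {
  bad <- energy_record("x", -400, 4, mono(3, 0, 1))
  expect_error(apply_monomer_correction(bad), class = "polyscape_value_error")

  once <- apply_monomer_correction(energy_record("x", -400, 4, mono(4, 0, 1)))
  expect_error(apply_monomer_correction(once), class = "polyscape_state_error")
})

test_that("the correction is additive in the monomer deltas", {
  set.seed(5)
  for (i in 1:10) {
    e <- runif(1, -500, -300)
    d1 <- rnorm(2)
    d2 <- rnorm(2)
    a <- apply_monomer_correction(
      energy_record("x", e, 4, mono(c(2, 2), 0, d1)))
    b <- apply_monomer_correction(
      energy_record("x", a$e_corrected_cell, 4, mono(c(2, 2), 0, d2)))
    both <- apply_monomer_correction(
      energy_record("x", e, 4, mono(c(2, 2), 0, d1 + d2)))
    expect_equal(b$e_corrected_cell, both$e_corrected_cell, tolerance = 1e-12)
  }
})

test_that("relative energies are gauge-invariant and reference to zero", {
  recs <- correct_records(list(
    energy_record("a", -400, 4, mono(4, 0, 0)),
    energy_record("b", -385.6, 4, mono(4, 0, 0))))
  rel <- relative_energies(recs, "a")
  expect_equal(unname(rel["a"]), 0)
  expect_equal(unname(rel["b"]), 3.6)

  # shifting every cell energy by a constant per molecule changes nothing
  recs2 <- correct_records(list(
    energy_record("a", -400 + 4 * 7, 4, mono(4, 0, 0)),
    energy_record("b", -385.6 + 4 * 7, 4, mono(4, 0, 0))))
  expect_equal(relative_energies(recs2, "a"), rel)

  expect_error(relative_energies(recs, "zz"), class = "polyscape_value_error")
  expect_equal(unname(relative_energies(c(a = -100), "a")), 0)
})

test_that("RMSE against experiment matches hand arithmetic", {
  expect_equal(rmse_vs_experiment(c(Y = 0, R = 1.2), c(Y = 0, R = 1.2), "Y"), 0)
  expect_equal(rmse_vs_experiment(c(Y = 0, R = 2), c(Y = 0, R = 1), "Y"), 1.0)
  expect_error(rmse_vs_experiment(c(Y = 0, R = 2), c(Y = 0, OP = 1), "Y"),
               class = "polyscape_value_error")
})

test_that("RMSE is invariant to a consistent change of reference form", {
  set.seed(6)
  forms <- c("Y", "YT04", "R", "OP", "ON")
  pred <- setNames(c(0, runif(4, 0, 6)), forms)
  ex <- setNames(c(0, runif(4, 0, 6)), forms)
  r1 <- rmse_vs_experiment(pred, ex, "Y")
  # expressing both input sets relative to any other form changes nothing,
  # because both are re-referenced internally to the stated reference
  for (g in forms) {
    expect_equal(rmse_vs_experiment(pred - pred[[g]], ex - ex[[g]], "Y"), r1,
                 tolerance = 1e-12)
  }
})

test_that("ranking comparison lists exactly the inverted pairs", {
  expect_equal(nrow(ranking_comparison(c("Y", "R", "OP"), c("Y", "R", "OP"))), 0)

  # one adjacent swap -> that single pair, flagged adjacent
  inv <- ranking_comparison(c("Y", "OP", "R"), c("Y", "R", "OP"))
  expect_equal(nrow(inv), 1)
  expect_equal(inv$form_a, "R")
  expect_equal(inv$form_b, "OP")
  expect_true(inv$adjacent)

  # random permutations against a brute-force O(n^2) inversion count
  set.seed(7)
  forms <- letters[1:8]
  for (i in 1:20) {
    pred <- sample(forms)
    inv <- ranking_comparison(pred, forms)
    pos <- match(forms, pred)
    brute <- sum(outer(seq_along(pos), seq_along(pos),
                       function(i, j) i < j & pos[i] > pos[j]))
    expect_equal(nrow(inv), brute)
  }
})

test_that("energy tables round-trip through CSV", {
  gen <- generate_landscape(synthetic_config(n_structures = 6, seed = 3,
                                             make_structures = FALSE))
  fc <- withr::local_tempfile(fileext = ".csv")
  fm <- withr::local_tempfile(fileext = ".csv")
  write.csv(gen$energies, fc, row.names = FALSE)
  write.csv(gen$monomers, fm, row.names = FALSE)
  recs <- read_energy_tables(fc, fm)
  expect_length(recs, 6)
  corr <- correct_records(recs)
  e <- vapply(corr, function(r) r$e_per_molecule, numeric(1))
  expect_equal(unname(e), gen$truth$e_true_per_molecule, tolerance = 1e-9)
})

test_that("unit converters use CODATA factors", {
  expect_equal(hartree_to_kjmol(1), 2625.4996394799)
  expect_equal(ev_to_kjmol(1), 96.48533212331)
})
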