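test_that("toy molecules have exactly one torsion path and rigid internals", {
  m <- generate_toy_molecule(118)
  expect_length(m$elements, 10)
  expect_equal(sum(m$elements == "S"), 1)
  expect_equal(sum(m$elements == "N"), 1)
  expect_equal(measure_dihedral(m), 118, tolerance = 1e-6)
  expect_equal(measure_dihedral(generate_toy_molecule(0)), 0, tolerance = 1e-9)
  expect_equal(measure_dihedral(generate_toy_molecule(180)), 180,
               tolerance = 1e-9)
  expect_error(generate_toy_molecule(190), class = "polyscape_value_error")
  # bond graph is connected and theta-independent
  expect_equal(nrow(m$bonds), 9)
  expect_equal(nrow(generate_toy_molecule(7)$bonds), 9)
})

test_that("generated crystals respect packing and symmetry", {
  m <- generate_toy_molecule(90)
  st1 <- generate_crystal(m, list(spacegroup = "P1"), id = "a", seed = 1)
  mols <- extract_molecules(st1)
  expect_length(mols, 1)
  expect_lt(kabsch(m$coords, mols[[1]]$coords, allow_inversion = TRUE)$rmsd,
            1e-8)

  st2 <- generate_crystal(m, list(spacegroup = "P21"), id = "b", seed = 2)
  mols2 <- extract_molecules(st2)
  expect_length(mols2, 2)
  expect_equal(measure_dihedral(mols2[[1]]), measure_dihedral(mols2[[2]]),
               tolerance = 1e-9)

  # an overly small cell cannot host the molecule without contacts
  expect_error(
    generate_crystal(m, list(spacegroup = "P1", cell_range = c(4, 4.5)),
                     seed = 3, max_attempts = 50),
    class = "polyscape_value_error")
})

test_that("the generator is a pure function of the seed", {
  cfg <- synthetic_config(n_structures = 6, seed = 123, duplicate_fraction = 0.2)
  g1 <- generate_landscape(cfg)
  g2 <- generate_landscape(cfg)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$energies, g2$energies)
  f1 <- withr::local_tempfile(fileext = ".cif")
  f2 <- withr::local_tempfile(fileext = ".cif")
  write_cif(g1$structures[[3]], f1)
  write_cif(g2$structures[[3]], f2)
  expect_identical(readLines(f1), readLines(f2))

  g3 <- generate_landscape(synthetic_config(n_structures = 6, seed = 124,
                                            duplicate_fraction = 0.2))
  expect_false(identical(g3$truth$theta, g1$truth$theta))
})

test_that("planted bias and monomer pairs obey the construction invariants", {
  cfg <- synthetic_config(n_structures = 20, bias_strength = 7, seed = 9,
                          make_structures = FALSE)
  g <- generate_landscape(cfg)
  expect_equal(g$monomers$e_target - g$monomers$e_base,
               planarity_bias(g$truth$theta, 7), tolerance = 1e-12)
  expect_equal(g$truth$e_base_cell / g$truth$z_total,
               g$truth$e_true_per_molecule - planarity_bias(g$truth$theta, 7),
               tolerance = 1e-12)
})

test_that("with zero bias the base ranking equals the true ranking", {
  g <- generate_landscape(synthetic_config(n_structures = 30, bias_strength = 0,
                                           seed = 10, make_structures = FALSE))
  base_rank <- order(order(g$truth$e_base_cell / g$truth$z_total,
                           g$truth$structure_id))
  expect_equal(base_rank, g$truth$intended_rank)
})

test_that("round trip: generated structures re-read to their planted theta", {
  g <- generate_landscape(synthetic_config(n_structures = 4, seed = 11,
                                           packing_noise = 0))
  dir <- withr::local_tempdir()
  write_synthetic_landscape(g, dir)
  for (i in seq_len(4)) {
    st <- read_cif(file.path(dir, paste0(g$truth$structure_id[i], ".cif")))
    m <- extract_molecules(st)[[1]]
    expect_equal(measure_dihedral(m), g$truth$theta[i], tolerance = 1e-5)
  }
  expect_true(file.exists(file.path(dir, "energies.csv")))
  expect_true(file.exists(file.path(dir, "monomers.csv")))
})

test_that("end-to-end pipeline recovers ranking and duplicate partition", {
  for (delta in c(0, 5, 20)) {
    g <- generate_landscape(synthetic_config(
      n_structures = 40, bias_strength = delta, packing_noise = 0,
      duplicate_fraction = 0.15, jitter = 0.05, seed = 200 + delta))
    recs <- correct_records(g$records)
    ls <- build_landscape(recs)
    # corrected energies equal truth
    e <- vapply(recs[g$truth$structure_id], function(r) r$e_per_molecule,
                numeric(1))
    expect_lt(max(abs(e - g$truth$e_true_per_molecule)), 1e-9)
    # dedup recovers the planted partition exactly
    out <- deduplicate(ls, g$structures, rmsd_tol = 0.3, energy_tol = 0.5)
    planted <- split(g$truth$structure_id, g$truth$duplicate_group)
    planted_pairs <- sort(unlist(lapply(planted[lengths(planted) > 1],
                                        function(grp) {
      apply(utils::combn(sort(grp), 2), 2, paste, collapse = "|")
    }), use.names = FALSE))
    merged_groups <- split(c(out$merges$kept, out$merges$removed),
                           rep(seq_len(nrow(out$merges)), 2))
    # reconstruct merged partition pairs from the log (kept/removed chains)
    gid <- setNames(g$truth$structure_id, g$truth$structure_id)
    for (k in seq_len(nrow(out$merges))) {
      gid[out$merges$removed[k]] <- gid[out$merges$kept[k]]
    }
    found <- split(names(gid), unname(gid))
    found_pairs <- sort(unlist(lapply(found[lengths(found) > 1],
                                      function(grp) {
      apply(utils::combn(sort(grp), 2), 2, paste, collapse = "|")
    }), use.names = FALSE))
    expect_equal(found_pairs, planted_pairs)
  }
})
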