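rec <- function(id, e_cell, z = 1) {
  apply_monomer_correction(energy_record(
    id, e_cell, z, data.frame(monomer_id = "m1", multiplicity = z,
                              e_base = 0, e_target = 0)))
}

test_that("landscapes rank by per-molecule relative energy", {
  ls <- build_landscape(list(rec("a", -100), rec("b", -99), rec("c", -98)))
  expect_equal(ls$rank, 1:3)
  expect_equal(ls$structure_id, c("a", "b", "c"))
  expect_equal(ls$rel_energy, c(0, 1, 2))
})

test_that("exact energy ties break lexicographically by id", {
  ls <- build_landscape(list(rec("zzz", -100), rec("aaa", -100), rec("mm", -99)))
  expect_equal(ls$structure_id, c("aaa", "zzz", "mm"))
  expect_equal(ls$rel_energy[1:2], c(0, 0))
  expect_equal(ls$rank, 1:3)
  expect_error(build_landscape(list(rec("a", -1), rec("a", -2))),
               class = "polyscape_value_error")
})

test_that("window counts are inclusive, filterable and monotone", {
  ls <- build_landscape(list(rec("a", -100), rec("b", -99), rec("c", -98)))
  expect_equal(count_in_window(ls, 1), 2)
  expect_equal(count_in_window(ls, 0.999), 1)
  expect_equal(count_in_window(ls, 10), 3)
  expect_error(count_in_window(ls, -1), class = "polyscape_value_error")

  ls$experimental_label[ls$structure_id == "a"] <- "Y"
  unknown <- function(df) is.na(df$experimental_label)
  expect_equal(count_in_window(ls, 10, unknown), 2)
  expect_equal(count_in_window(ls, 10, "Y"), 1)

  # monotone nondecreasing in the window (randomised)
  set.seed(8)
  e <- sort(runif(50, 0, 20))
  ls2 <- build_landscape(setNames(e, sprintf("s%02d", 1:50)))
  ws <- sort(runif(20, 0, 20))
  counts <- vapply(ws, function(w) count_in_window(ls2, w), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("landscapes built on structures carry density, theta and color", {
  gen <- generate_landscape(synthetic_config(n_structures = 8, seed = 77,
                                             packing_noise = 0.5))
  ls <- build_landscape(correct_records(gen$records), gen$structures)
  expect_true(all(is.finite(ls$density)))
  expect_true(all(ls$color_class %in% c("yellow", "red_orange")))
  i <- match(ls$structure_id, gen$truth$structure_id)
  expect_equal(ls$theta, gen$truth$theta[i], tolerance = 1e-6)
  expect_equal(ls$rank, order(order(gen$truth$intended_rank[i])))
})

test_that("duplicates merge only when both energy and packing agree", {
  st <- toy_crystal(95, seed = 41, id = "a")
  dup <- withr::with_seed(42, jitter_structure(st, 0.03))
  dup$id <- "b"
  far <- toy_crystal(95, seed = 43, id = "c") # same energy, different packing
  sts <- list(a = st, b = dup, c = far)
  ls <- build_landscape(list(rec("a", -100), rec("b", -99.9), rec("c", -100)))

  out <- deduplicate(ls, sts, rmsd_tol = 0.3, energy_tol = 0.5)
  expect_equal(nrow(out$merges), 1)
  expect_equal(out$merges$kept, "a")
  expect_equal(out$merges$removed, "b")
  expect_equal(sort(out$landscape$structure_id), c("a", "c"))
  expect_equal(out$landscape$rank, 1:2)

  # energy agreement alone is not enough: a and c both survive
  expect_false("c" %in% out$merges$removed)

  # idempotence
  out2 <- deduplicate(out$landscape, sts, rmsd_tol = 0.3, energy_tol = 0.5)
  expect_equal(nrow(out2$merges), 0)

  # tight energy tolerance keeps the jittered twin
  out3 <- deduplicate(ls, sts, rmsd_tol = 0.3, energy_tol = 0.05)
  expect_equal(nrow(out3$merges), 0)
})

test_that("experimental labelling assigns best matches one-to-one", {
  a <- toy_crystal(118, seed = 51, id = "a")
  b <- toy_crystal(40, seed = 52, id = "b")
  sts <- list(a = a, b = b)
  ls <- build_landscape(list(rec("a", -100), rec("b", -98)))

  # reference identical to one candidate labels it
  refY <- a
  refY$id <- "Y"
  out <- label_experimental(ls, sts, list(Y = refY))
  expect_equal(out$experimental_label[out$structure_id == "a"], "Y")
  expect_true(is.na(out$experimental_label[out$structure_id == "b"]))
  expect_length(attr(out, "unmatched"), 0)

  # two candidates under tolerance: the lower-RMSD one is labelled
  near <- withr::with_seed(53, jitter_structure(a, 0.02))
  near$id <- "c"
  sts2 <- list(a = a, c = near)
  ls2 <- build_landscape(list(rec("a", -100), rec("c", -99.9)))
  ref2 <- withr::with_seed(54, jitter_structure(a, 0.001))
  ref2$id <- "Y"
  out2 <- label_experimental(ls2, sts2, list(Y = ref2))
  expect_equal(out2$experimental_label[out2$structure_id == "a"], "Y")

  # a reference matching nothing is reported unmatched
  refX <- toy_crystal(150, seed = 55, id = "X")
  out3 <- label_experimental(ls, sts, list(X = refX))
  expect_true(all(is.na(out3$experimental_label)))
  expect_equal(attr(out3, "unmatched"), "X")
})
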