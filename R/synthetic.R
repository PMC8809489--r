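# Seeded synthetic crystal landscapes. Each structure hosts a rigid 10-atom
# toy molecule with a single S-C-N-C torsion theta. True per-molecule energies
# are a double-well conformational term plus a packing term; the "base" energy
# model is biased by -delta*cos^2(theta), which spuriously stabilises planar
# conformations (the delocalization-error analogue). Matching gas-phase
# monomer energy pairs satisfy e_target - e_base = +delta*cos^2(theta), so the
# monomer correction removes the bias exactly. Every quantity is a pure
# function of the seed.

#' Double-well conformational energy
#'
#' `w(theta) = w0 * sin^2(2 * (theta - theta0))` with minima at `theta0` and
#' `theta0 + 90` degrees (defaults 45/135) and barriers near 0, 90 and 180.
#'
#' @param theta torsion angle(s) in degrees.
#' @param w0 barrier height in kJ/mol.
#' @param theta0 location of the first minimum in degrees.
#' @return Conformational energies in kJ/mol.
#' @export
conformational_energy <- function(theta, w0 = 6, theta0 = 45) {
  w0 * sin(2 * (theta - theta0) * pi / 180)^2
}

#' Planarity bias of the base energy model
#'
#' `bias(theta) = delta * cos^2(theta)`: maximal for planar conformations
#' (theta near 0 or 180), zero at 90 degrees. The base model's crystal energy
#' is the true energy minus this bias.
#'
#' @param theta torsion angle(s) in degrees.
#' @param delta bias strength in kJ/mol.
#' @return Bias energies in kJ/mol.
#' @export
planarity_bias <- function(theta, delta) {
  delta * cos(theta * pi / 180)^2
}

#' Configuration for the synthetic landscape generator
#'
#' @param n_structures number of structures on the landscape (duplicates
#'   included).
#' @param bias_strength planarity-bias strength delta in kJ/mol.
#' @param packing_noise standard deviation sigma (kJ/mol) of the uniform
#'   packing term folded into the true energies.
#' @param dihedral_mixture list of mixture components for the torsion
#'   distribution over `[0, 180]` degrees; each component is
#'   `list(weight=, mean=, sd=)` (truncated normal) or
#'   `list(weight=, min=, max=)` (uniform).
#' @param duplicate_fraction fraction of structures that are jittered copies
#'   of another structure.
#' @param jitter Cartesian jitter sigma (Angstrom) applied to duplicate
#'   copies.
#' @param seed integer seed; fully determines the output.
#' @param w0,theta0 double-well parameters (see [conformational_energy()]).
#' @param p21_fraction fraction of structures generated in P2_1 (Z = 2)
#'   rather than P1 (Z = 1).
#' @param make_structures generate crystal structures (`TRUE`) or only the
#'   energy tables and truth (fast path for ranking studies).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_structures = 100, bias_strength = 10,
                             packing_noise = 1,
                             dihedral_mixture = list(
                               list(weight = 0.45, mean = 45, sd = 25),
                               list(weight = 0.45, mean = 135, sd = 25),
                               list(weight = 0.10, min = 0, max = 180)),
                             duplicate_fraction = 0, jitter = 0.05,
                             seed = 1, w0 = 6, theta0 = 45,
                             p21_fraction = 0.2, make_structures = TRUE) {
  vals <- c(n_structures, bias_strength, packing_noise, duplicate_fraction,
            jitter, w0)
  if (any(vals < 0)) ps_value_error("config values must be nonnegative")
  if (duplicate_fraction >= 1) ps_value_error("duplicate_fraction must be < 1")
  structure(list(n_structures = as.integer(n_structures),
                 bias_strength = bias_strength,
                 packing_noise = packing_noise,
                 dihedral_mixture = dihedral_mixture,
                 duplicate_fraction = duplicate_fraction,
                 jitter = jitter, seed = as.integer(seed),
                 w0 = w0, theta0 = theta0,
                 p21_fraction = p21_fraction,
                 make_structures = isTRUE(make_structures)),
            class = "synthetic_config")
}

# sample torsions from the mixture, by rejection for truncated normals
.sample_dihedrals <- function(n, mixture) {
  w <- vapply(mixture, function(m) m$weight, numeric(1))
  comp <- sample.int(length(mixture), n, replace = TRUE, prob = w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    m <- mixture[[comp[i]]]
    if (!is.null(m$mean)) {
      repeat {
        x <- stats::rnorm(1, m$mean, m$sd)
        if (x >= 0 && x <= 180) break
      }
      out[i] <- x
    } else {
      out[i] <- stats::runif(1, m$min %||% 0, m$max %||% 180)
    }
  }
  out
}

#' Build the rigid toy molecule at a given torsion
#'
#' A 10-heavy-atom molecule containing exactly one S-C-N-C path whose torsion
#' equals `theta` by construction (internal-coordinate placement). All other
#' internal coordinates are fixed.
#'
#' @param theta torsion angle in degrees, in `[0, 180]`.
#' @return A `molecule` object (see [molecule()]).
#' @export
generate_toy_molecule <- function(theta) {
  if (!is.finite(theta) || theta < 0 || theta > 180) {
    ps_value_error("theta must lie in [0, 180] degrees")
  }
  # fixed fragment: C2 at origin, N3 along x, S1 in the xy plane
  c2 <- c(0, 0, 0)
  n3 <- c(1.38, 0, 0)
  s1 <- c2 + 1.75 * c(cos(120 * pi / 180), sin(120 * pi / 180), 0)
  # torsion-defining atom
  c4 <- place_atom(s1, c2, n3, 1.40, 122, theta)
  # substituents riding on the C4 frame
  c5 <- place_atom(c2, n3, c4, 1.45, 118, 180)
  c6 <- place_atom(n3, c4, c5, 1.40, 121, 180)
  c7 <- place_atom(c4, c5, c6, 1.42, 119, 180)
  o8 <- place_atom(c5, c6, c7, 1.24, 120, 0)
  # substituents on the fixed fragment (theta-independent)
  c9 <- place_atom(s1, n3, c2, 1.48, 121, 180)
  c10 <- place_atom(n3, c2, c9, 1.50, 113, 90)
  coords <- rbind(s1, c2, n3, c4, c5, c6, c7, o8, c9, c10)
  elements <- c("S", "C", "N", "C", "C", "C", "C", "O", "C", "C")
  labels <- c("S1", "C2", "N3", "C4", "C5", "C6", "C7", "O8", "C9", "C10")
  rownames(coords) <- NULL
  molecule(elements, coords, labels)
}

# shortest intermolecular heavy-atom contact between all expanded molecules,
# across periodic images
.min_intermolecular_contact <- function(structure, tolerance = 1.2) {
  ex <- expand_sites(structure)
  frac <- as.matrix(ex[, c("fx", "fy", "fz")])
  cart <- frac_to_cart(frac, structure$cell)
  heavy <- ex$element != "H"
  cart <- cart[heavy, , drop = FALSE]
  op <- ex$op_index[heavy]
  m <- cell_matrix(structure$cell)
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    shift <- as.numeric(m %*% c(i, j, k))
    d2 <- outer(rowSums(cart^2), rowSums(sweep(cart, 2, -shift)^2), `+`) -
      2 * cart %*% t(sweep(cart, 2, -shift))
    d <- sqrt(pmax(d2, 0))
    same_cell <- (i == 0 && j == 0 && k == 0)
    intra <- outer(op, op, `==`) & same_cell
    diag(intra) <- TRUE
    d[intra] <- Inf
    if (same_cell) d[d < 1e-6] <- Inf
    best <- min(best, min(d))
  }
  best
}

#' Generate a toy molecular crystal
#'
#' Places the molecule at a random position and orientation in a randomized
#' cell of the requested space group (P1, Z = 1 or P2_1, Z = 2), rejecting
#' placements with any intermolecular heavy-atom contact below `min_contact`.
#'
#' @param mol a molecule (e.g. from [generate_toy_molecule()]).
#' @param packing list with `spacegroup` (`"P1"` or `"P21"`) and optionally
#'   `cell_range` (length-2 vector of cell-edge bounds in Angstrom).
#' @param id structure id.
#' @param seed optional integer seed (when `NULL`, the current RNG stream is
#'   used).
#' @param min_contact minimum allowed intermolecular heavy-atom distance
#'   (Angstrom).
#' @param max_attempts placement attempts before a placement error is raised.
#' @return A [crystal_structure()] with `z_total`/`z_prime` set.
#' @export
generate_crystal <- function(mol, packing = list(spacegroup = "P1"),
                             id = "synth", seed = NULL, min_contact = 2.5,
                             max_attempts = 10000) {
  if (!is.null(seed)) set.seed(seed)
  sg <- toupper(packing$spacegroup %||% "P1")
  if (!sg %in% c("P1", "P21")) {
    ps_value_error("supported packings are P1 (Z = 1) and P21 (Z = 2)")
  }
  rng <- packing$cell_range %||% c(12, 15)
  ops <- if (sg == "P1") list(identity_symop()) else spacegroup_ops("P21")
  z <- length(ops)
  coords0 <- sweep(mol$coords, 2, colMeans(mol$coords))
  for (attempt in seq_len(max_attempts)) {
    cell <- unit_cell(stats::runif(1, rng[1], rng[2]),
                      stats::runif(1, rng[1], rng[2]),
                      stats::runif(1, rng[1], rng[2]),
                      if (sg == "P1") stats::runif(1, 80, 100) else 90,
                      stats::runif(1, 80, 100),
                      if (sg == "P1") stats::runif(1, 80, 100) else 90)
    rot <- random_rotation_matrix()
    pos <- stats::runif(3, 0.2, 0.8)
    cart <- sweep(coords0 %*% t(rot), 2, frac_to_cart(pos, cell), `+`)
    frac <- cart_to_frac(cart, cell)
    sites <- data.frame(label = mol$labels, element = mol$elements,
                        fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
                        stringsAsFactors = FALSE)
    st <- crystal_structure(id, cell, ops, sites, z_total = z, z_prime = 1L)
    if (.min_intermolecular_contact(st) >= min_contact) return(st)
  }
  ps_value_error(sprintf(
    "could not place the molecule without contacts < %.2f A after %d attempts",
    min_contact, max_attempts))
}

#' Apply Cartesian jitter to a structure's sites
#'
#' @param structure a [crystal_structure()].
#' @param sigma per-coordinate Gaussian jitter in Angstrom.
#' @return The jittered structure.
#' @export
jitter_structure <- function(structure, sigma) {
  frac <- as.matrix(structure$sites[, c("fx", "fy", "fz")])
  cart <- frac_to_cart(frac, structure$cell)
  cart <- cart + matrix(stats::rnorm(length(cart), 0, sigma), ncol = 3)
  frac <- cart_to_frac(cart, structure$cell)
  structure$sites$fx <- frac[, 1] - floor(frac[, 1])
  structure$sites$fy <- frac[, 2] - floor(frac[, 2])
  structure$sites$fz <- frac[, 3] - floor(frac[, 3])
  structure
}

#' Generate a synthetic crystal energy landscape
#'
#' Draws torsions from the configured mixture, builds toy crystals, assigns
#' true per-molecule energies (double well + packing term), derives biased
#' base crystal energies (`true - delta * cos^2(theta)` per molecule) and
#' matching monomer energy pairs (`e_target - e_base = delta * cos^2(theta)`),
#' and plants jittered near-duplicates. The monomer correction therefore
#' recovers the true energies exactly.
#'
#' @param config a [synthetic_config()].
#' @return List with `structures` (named list, or `NULL` when
#'   `make_structures = FALSE`), `records` (uncorrected [energy_record()]s),
#'   `energies`/`monomers` (the same data as CSV-ready data frames) and
#'   `truth` (data frame with `structure_id`, `theta`, `e_true_per_molecule`,
#'   `e_base_cell`, `z_total`, `duplicate_group`, `intended_rank`).
#' @export
generate_landscape <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_structures
  n_dup <- round(config$duplicate_fraction * n)
  n_base <- n - n_dup
  if (n_base < 1) ps_value_error("duplicate_fraction leaves no base structures")

  theta <- .sample_dihedrals(n_base, config$dihedral_mixture)
  packing <- stats::runif(n_base, -config$packing_noise * sqrt(3),
                          config$packing_noise * sqrt(3))
  # spread of packing energies across the landscape beyond the noise term
  packing <- packing + stats::runif(n_base, 0, 12)
  e_true <- conformational_energy(theta, config$w0, config$theta0) + packing
  sg <- ifelse(stats::runif(n_base) < config$p21_fraction, "P21", "P1")

  parents <- if (n_dup > 0) sample.int(n_base, n_dup, replace = TRUE) else integer(0)

  ids <- sprintf("str%03d", seq_len(n))
  theta_all <- c(theta, theta[parents])
  e_true_all <- c(e_true, e_true[parents])
  sg_all <- c(sg, sg[parents])
  dup_group <- c(ids[seq_len(n_base)], ids[parents])

  z_all <- ifelse(sg_all == "P21", 2L, 1L)
  bias <- planarity_bias(theta_all, config$bias_strength)
  e_base_cell <- (e_true_all - bias) * z_all

  mono_base <- stats::runif(n, -5, 5)
  energies <- data.frame(structure_id = ids, e_crystal_cell = e_base_cell,
                         z_total = z_all, stringsAsFactors = FALSE)
  monomers <- data.frame(structure_id = ids,
                         monomer_id = paste0(ids, "_m1"),
                         multiplicity = z_all,
                         e_base = mono_base,
                         e_target = mono_base + bias,
                         stringsAsFactors = FALSE)

  structures <- NULL
  if (config$make_structures) {
    structures <- vector("list", n)
    for (i in seq_len(n_base)) {
      mol <- generate_toy_molecule(theta[i])
      structures[[i]] <- generate_crystal(
        mol, packing = list(spacegroup = sg[i]), id = ids[i])
    }
    for (k in seq_len(n_dup)) {
      i <- n_base + k
      st <- structures[[parents[k]]]
      st$id <- ids[i]
      structures[[i]] <- jitter_structure(st, config$jitter)
    }
    names(structures) <- ids
  }

  records <- lapply(seq_len(n), function(i) {
    energy_record(ids[i], e_base_cell[i], z_all[i],
                  monomers[monomers$structure_id == ids[i],
                           c("monomer_id", "multiplicity", "e_base",
                             "e_target")])
  })
  names(records) <- ids

  # 1-based rank by true energy, ties broken lexicographically by id
  intended_rank <- order(order(e_true_all, ids))

  truth <- data.frame(structure_id = ids, theta = theta_all,
                      e_true_per_molecule = e_true_all,
                      e_base_cell = e_base_cell, z_total = z_all,
                      duplicate_group = dup_group,
                      intended_rank = intended_rank,
                      stringsAsFactors = FALSE)
  list(structures = structures, records = records, energies = energies,
       monomers = monomers, truth = truth, config = config)
}

#' Generate two EOS-derived pressure series with a known crossover
#'
#' Samples each phase's analytic Birch-Murnaghan enthalpy on the pressure grid
#' (solving V(P) to 1e-10) and returns the analytic crossover pressures
#' alongside, for validating numeric crossover detection.
#'
#' @param eos_a,eos_b [eos_params()] for the two phases.
#' @param pressures pressure grid in GPa.
#' @param ids character vector of two series ids.
#' @return List with `series_a`, `series_b` ([pv_series()]) and `crossovers`
#'   (analytic crossover pressures in GPa, possibly empty).
#' @export
generate_pv_series <- function(eos_a, eos_b, pressures,
                               ids = c("phase_a", "phase_b")) {
  stopifnot(inherits(eos_a, "eos_params"), inherits(eos_b, "eos_params"))
  make <- function(eos, id) {
    v <- eos_volume_at_pressure(eos, pressures)
    e <- birch_murnaghan_energy(v, eos$e0, eos$v0, eos$b0, eos$b0p)
    pv_series(id, pressures, e, v)
  }
  sa <- make(eos_a, ids[1])
  sb <- make(eos_b, ids[2])
  dh <- function(p) eos_enthalpy(eos_a, p) - eos_enthalpy(eos_b, p)
  # locate analytic sign changes on a fine grid, then polish by bisection
  fine <- seq(min(pressures), max(pressures), length.out = 2001)
  roots <- .sign_change_roots(fine, dh(fine), dh, tol = 1e-10)
  list(series_a = sa, series_b = sb, crossovers = roots)
}

#' Write a generated landscape to disk
#'
#' Emits one CIF per structure plus `energies.csv`, `monomers.csv` and
#' `truth.csv` into a directory.
#'
#' @param landscape result of [generate_landscape()] (with structures).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_landscape <- function(landscape, dir) {
  if (is.null(landscape$structures)) {
    ps_value_error("landscape was generated without structures")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in landscape$structures) {
    write_cif(st, file.path(dir, paste0(st$id, ".cif")))
  }
  utils::write.csv(landscape$energies, file.path(dir, "energies.csv"),
                   row.names = FALSE)
  utils::write.csv(landscape$monomers, file.path(dir, "monomers.csv"),
                   row.names = FALSE)
  utils::write.csv(landscape$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
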