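# Monomer conformational-energy correction of crystal lattice energies.
#
# The corrected energy per unit cell replaces the crystal model's
# intramolecular conformational energy with a higher-level gas-phase monomer
# energy, summed over all molecules in the cell:
#
#   E_corrected(cell) = E_crystal(cell, base) +
#                       sum_i m_i * (E_mon,i(target) - E_mon,i(base))
#
# where i runs over the symmetrically unique monomers and m_i is the number of
# symmetry copies of monomer i per cell (sum of m_i equals Z). All landscape
# comparisons downstream are per molecule: E_corrected(cell) / Z.

KJMOL_PER_HARTREE <- 2625.4996394799
KJMOL_PER_EV <- 96.48533212331

#' Convert hartree to kJ/mol
#' @param x energies in hartree.
#' @return Energies in kJ/mol (CODATA factor).
#' @export
hartree_to_kjmol <- function(x) x * KJMOL_PER_HARTREE

#' Convert electronvolt to kJ/mol
#' @param x energies in eV.
#' @return Energies in kJ/mol (CODATA factor).
#' @export
ev_to_kjmol <- function(x) x * KJMOL_PER_EV

#' Construct an energy record for one crystal structure
#'
#' @param structure_id structure identifier.
#' @param e_crystal_cell crystal energy per unit cell at the base level
#'   (kJ/mol).
#' @param z_total molecules per unit cell.
#' @param monomers data frame with one row per symmetrically unique monomer:
#'   columns `monomer_id`, `multiplicity`, `e_base`, `e_target` (gas-phase
#'   monomer energies in kJ/mol at the base and target levels).
#' @return An object of class `energy_record` (uncorrected).
#' @export
energy_record <- function(structure_id, e_crystal_cell, z_total, monomers) {
  monomers <- as.data.frame(monomers, stringsAsFactors = FALSE)
  need <- c("monomer_id", "multiplicity", "e_base", "e_target")
  if (!all(need %in% names(monomers))) {
    ps_format_error("monomers must have columns monomer_id, multiplicity, e_base, e_target")
  }
  if (any(monomers$multiplicity < 1)) {
    ps_value_error("monomer multiplicities must be >= 1")
  }
  structure(list(structure_id = as.character(structure_id),
                 e_crystal_cell = e_crystal_cell,
                 z_total = as.integer(z_total),
                 monomers = monomers,
                 corrected = FALSE,
                 e_corrected_cell = NULL,
                 e_per_molecule = NULL),
            class = "energy_record")
}

#' Apply the monomer conformational-energy correction
#'
#' Adds `sum(multiplicity * (e_target - e_base))` to the per-cell crystal
#' energy and derives the per-molecule energy. Records carry a corrected flag;
#' correcting a record twice is an error (silent double-correction is the
#' likeliest real-world bug).
#'
#' @param record an [energy_record()].
#' @return The corrected record, with `e_corrected_cell` and `e_per_molecule`
#'   filled in and `corrected = TRUE`.
#' @export
apply_monomer_correction <- function(record) {
  stopifnot(inherits(record, "energy_record"))
  if (isTRUE(record$corrected)) {
    ps_state_error(paste0("record '", record$structure_id,
                          "' has already been corrected"))
  }
  msum <- sum(record$monomers$multiplicity)
  if (msum != record$z_total) {
    ps_value_error(sprintf(
      "monomer multiplicities sum to %d but z_total is %d (structure '%s')",
      msum, record$z_total, record$structure_id))
  }
  delta <- sum(record$monomers$multiplicity *
                 (record$monomers$e_target - record$monomers$e_base))
  record$e_corrected_cell <- record$e_crystal_cell + delta
  record$e_per_molecule <- record$e_corrected_cell / record$z_total
  record$corrected <- TRUE
  record
}

#' Correct a list of energy records
#'
#' @param records list of [energy_record()]s.
#' @return List of corrected records, names set to structure ids.
#' @export
correct_records <- function(records) {
  out <- lapply(records, apply_monomer_correction)
  names(out) <- vapply(out, function(r) r$structure_id, character(1))
  out
}

.per_molecule_energies <- function(records) {
  if (is.numeric(records)) {
    if (is.null(names(records))) ps_value_error("energies must be named")
    return(records)
  }
  e <- vapply(records, function(r) {
    stopifnot(inherits(r, "energy_record"))
    if (!isTRUE(r$corrected)) {
      ps_state_error(paste0("record '", r$structure_id, "' is not corrected yet"))
    }
    r$e_per_molecule
  }, numeric(1))
  names(e) <- vapply(records, function(r) r$structure_id, character(1))
  e
}

#' Relative per-molecule energies against a reference structure
#'
#' @param records list of corrected [energy_record()]s, or a named numeric
#'   vector of per-molecule energies.
#' @param reference_id id of the reference structure (mapped to 0).
#' @return Named numeric vector of relative energies (kJ/mol per molecule).
#' @export
relative_energies <- function(records, reference_id) {
  e <- .per_molecule_energies(records)
  if (!reference_id %in% names(e)) {
    ps_value_error(paste0("reference structure '", reference_id, "' not found"))
  }
  e - e[[reference_id]]
}

#' RMSE of predicted relative energies against experimental enthalpies
#'
#' Both sets are re-referenced to the stated reference form; the RMSE is taken
#' over the non-reference forms, so it is invariant to the choice of reference
#' when both sets are re-referenced consistently.
#'
#' @param predicted named numeric vector of relative lattice energies (kJ/mol).
#' @param experimental named numeric vector of relative experimental
#'   enthalpies (kJ/mol).
#' @param reference name of the reference form (value 0 in both sets).
#' @return RMSE in kJ/mol.
#' @export
rmse_vs_experiment <- function(predicted, experimental, reference) {
  forms <- names(experimental)
  if (!setequal(forms, names(predicted))) {
    ps_value_error("predicted and experimental cover different form sets")
  }
  if (!reference %in% forms) ps_value_error("reference form not in the form set")
  p <- predicted[forms] - predicted[[reference]]
  x <- experimental[forms] - experimental[[reference]]
  keep <- forms != reference
  sqrt(mean((p[keep] - x[keep])^2))
}

#' Compare a predicted stability order with the experimental one
#'
#' Lists every pair of forms whose relative order is inverted between the two
#' orders (most stable first). The result is empty exactly when the orders are
#' identical; pairs adjacent in the experimental order are flagged.
#'
#' @param predicted character vector: forms in predicted stability order.
#' @param experimental character vector: forms in experimental stability order.
#' @return Data frame with columns `form_a`, `form_b` (experimental order:
#'   a before b) and `adjacent`.
#' @export
ranking_comparison <- function(predicted, experimental) {
  if (!setequal(predicted, experimental) ||
      length(predicted) != length(experimental)) {
    ps_value_error("predicted and experimental must order the same form set")
  }
  pos <- match(experimental, predicted)
  out <- data.frame(form_a = character(0), form_b = character(0),
                    adjacent = logical(0), stringsAsFactors = FALSE)
  n <- length(experimental)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (pos[i] > pos[j]) {
        out <- rbind(out, data.frame(form_a = experimental[i],
                                     form_b = experimental[j],
                                     adjacent = (j == i + 1),
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Read energy tables from CSV
#'
#' `crystal_csv` needs columns `structure_id`, `e_crystal_cell`, `z_total`;
#' `monomer_csv` is long format with `structure_id`, `monomer_id`,
#' `multiplicity`, `e_base`, `e_target`.
#'
#' @param crystal_csv,monomer_csv file paths.
#' @return List of (uncorrected) [energy_record()]s.
#' @export
read_energy_tables <- function(crystal_csv, monomer_csv) {
  cr <- utils::read.csv(crystal_csv, stringsAsFactors = FALSE)
  mo <- utils::read.csv(monomer_csv, stringsAsFactors = FALSE)
  need_cr <- c("structure_id", "e_crystal_cell", "z_total")
  need_mo <- c("structure_id", "monomer_id", "multiplicity", "e_base", "e_target")
  if (!all(need_cr %in% names(cr))) ps_format_error("bad crystal energy table header")
  if (!all(need_mo %in% names(mo))) ps_format_error("bad monomer energy table header")
  recs <- lapply(seq_len(nrow(cr)), function(i) {
    sub <- mo[mo$structure_id == cr$structure_id[i], need_mo[-1], drop = FALSE]
    if (!nrow(sub)) {
      ps_format_error(paste0("no monomer rows for structure ", cr$structure_id[i]))
    }
    energy_record(cr$structure_id[i], cr$e_crystal_cell[i], cr$z_total[i], sub)
  })
  names(recs) <- cr$structure_id
  recs
}

#' Write corrected energies to CSV
#'
#' @param records list of corrected [energy_record()]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_corrected_energies <- function(records, path) {
  e <- .per_molecule_energies(records)
  df <- data.frame(
    structure_id = names(e),
    e_corrected_cell = vapply(records, function(r) r$e_corrected_cell, numeric(1)),
    z_total = vapply(records, function(r) r$z_total, numeric(1)),
    e_per_molecule = unname(e)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
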