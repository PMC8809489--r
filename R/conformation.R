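# The key S-C-N-C torsion of conformational polymorphs: measurement, color
# classification and basin assignment, and the landscape conformation profile.
#
# Conventions (documented, deliberately deterministic):
#   * torsions are reported as |theta| in [0, 180] degrees;
#   * yellow iff 50 <= theta <= 130 (boundaries inclusive on the yellow side),
#     otherwise red/orange;
#   * basin A iff theta < 80, basin B otherwise (80 assigned upward).

#' Specify the torsion to measure
#'
#' Either four explicit atom labels (in order) or an element-path pattern
#' traced through the bond graph (default `"S-C-N-C"`). A pattern must resolve
#' to exactly one ordered atom quadruple per molecule, with consecutive atoms
#' bonded and the central N bonded to at least two carbons; ambiguity is an
#' error, not a guess.
#'
#' @param labels optional character vector of four site labels.
#' @param pattern element-path pattern, elements separated by `-`.
#' @return An object of class `dihedral_spec`.
#' @export
dihedral_spec <- function(labels = NULL, pattern = "S-C-N-C") {
  if (!is.null(labels) && length(labels) != 4) {
    ps_value_error("labels must name exactly four atoms")
  }
  structure(list(labels = labels,
                 pattern = strsplit(pattern, "-", fixed = TRUE)[[1]]),
            class = "dihedral_spec")
}

.resolve_dihedral <- function(mol, spec) {
  stopifnot(inherits(mol, "molecule"), inherits(spec, "dihedral_spec"))
  if (!is.null(spec$labels)) {
    idx <- match(spec$labels, mol$labels)
    if (anyNA(idx)) ps_value_error("dihedral labels not found in molecule")
    return(idx)
  }
  pat <- spec$pattern
  if (length(pat) != 4) ps_value_error("element-path pattern must have four atoms")
  n <- length(mol$elements)
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  quads <- list()
  for (a1 in which(mol$elements == pat[1])) {
    for (a2 in intersect(adj[[a1]], which(mol$elements == pat[2]))) {
      for (a3 in setdiff(intersect(adj[[a2]], which(mol$elements == pat[3])), a1)) {
        for (a4 in setdiff(intersect(adj[[a3]], which(mol$elements == pat[4])),
                           c(a1, a2))) {
          quads[[length(quads) + 1]] <- c(a1, a2, a3, a4)
        }
      }
    }
  }
  if (identical(pat, c("S", "C", "N", "C")) && length(quads) > 1) {
    # disambiguate: require the N to bridge two carbons
    ok <- vapply(quads, function(q) {
      sum(mol$elements[adj[[q[3]]]] == "C") >= 2
    }, logical(1))
    quads <- quads[ok]
  }
  if (!length(quads)) ps_value_error("dihedral pattern not found in molecule")
  if (length(quads) > 1) {
    ps_value_error("dihedral pattern is ambiguous (multiple matching paths)")
  }
  quads[[1]]
}

#' Measure the specified torsion of a molecule
#'
#' @param mol a molecule (see [extract_molecules()] / [molecule()]).
#' @param spec a [dihedral_spec()].
#' @return Absolute torsion angle in degrees, in `[0, 180]`.
#' @export
measure_dihedral <- function(mol, spec = dihedral_spec()) {
  idx <- .resolve_dihedral(mol, spec)
  abs(torsion_angle(mol$coords[idx[1], ], mol$coords[idx[2], ],
                    mol$coords[idx[3], ], mol$coords[idx[4], ]))
}

#' Classify polymorph color from the torsion angle
#'
#' Near-perpendicular conformations (50-130 degrees) retain the twisted,
#' weakly conjugated chromophore of yellow forms; flatter conformations gain
#' pi conjugation and shift toward red/orange.
#'
#' @param theta torsion angle(s) in degrees, each in `[0, 180]`.
#' @return Character vector: `"yellow"` or `"red_orange"`.
#' @export
classify_color <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 180)) {
    ps_value_error("theta must lie in [0, 180] degrees")
  }
  ifelse(theta >= 50 & theta <= 130, "yellow", "red_orange")
}

#' Assign the conformational basin from the torsion angle
#'
#' The gas-phase conformational profile has two basins separated by a barrier
#' near 80 degrees; the boundary value is assigned upward (basin B).
#'
#' @param theta torsion angle(s) in degrees, each in `[0, 180]`.
#' @return Character vector: `"A"` (theta < 80) or `"B"`.
#' @export
assign_basin <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 180)) {
    ps_value_error("theta must lie in [0, 180] degrees")
  }
  ifelse(theta < 80, "A", "B")
}

#' Conformation-energy profile of a landscape
#'
#' Measures the key torsion for every structure (one row per unique molecule
#' for Z' > 1 structures), classifies color and basin, and tabulates per-color
#' and per-basin counts inside an energy window.
#'
#' @param structures named list of [crystal_structure()]s.
#' @param rel_energies named numeric vector of relative energies (kJ/mol per
#'   molecule), names matching `structures`.
#' @param window energy window (kJ/mol) for the counts; entries with
#'   `rel_energy <= window` are counted (inclusive).
#' @param spec a [dihedral_spec()].
#' @param tolerance bond-perception tolerance.
#' @return Data frame with columns `structure_id`, `theta`, `rel_energy`,
#'   `color_class`, `basin`, plus attributes `color_counts` and `basin_counts`
#'   (tables over the in-window rows) and `window`.
#' @export
conformation_profile <- function(structures, rel_energies, window = Inf,
                                 spec = dihedral_spec(), tolerance = 1.2) {
  ids <- names(structures)
  if (is.null(ids) || !all(ids %in% names(rel_energies))) {
    ps_value_error("structures and rel_energies must share names")
  }
  rows <- list()
  for (id in ids) {
    mols <- extract_molecules(structures[[id]], tolerance)
    uniq <- mols[vapply(mols, function(m) m$op_index == 1L, logical(1))]
    if (!length(uniq)) uniq <- mols[1]
    for (m in uniq) {
      th <- measure_dihedral(m, spec)
      rows[[length(rows) + 1]] <- data.frame(
        structure_id = id, theta = th,
        rel_energy = unname(rel_energies[id]),
        color_class = classify_color(th), basin = assign_basin(th),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  inw <- out[out$rel_energy <= window, , drop = FALSE]
  attr(out, "color_counts") <- table(factor(inw$color_class,
                                            c("yellow", "red_orange")))
  attr(out, "basin_counts") <- table(factor(inw$basin, c("A", "B")))
  attr(out, "window") <- window
  out
}
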