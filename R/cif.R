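# Crystal structures and a practical CIF subset: cell parameters, symmetry
# (explicit xyz loop or Hermann-Mauguin symbol), and fractional atom sites.
# Fully ordered structures only; occupancies other than 1 are rejected.

#' Construct a crystal structure
#'
#' @param id structure identifier.
#' @param cell a [unit_cell()].
#' @param ops list of [symop()]s; the identity is moved/prepended to position 1.
#' @param sites data frame with columns `label`, `element`, `fx`, `fy`, `fz`
#'   (fractional coordinates, reduced to `[0, 1)` on construction). One row per
#'   asymmetric-unit atom; labels must be unique.
#' @param z_total,z_prime optional molecule counts per cell / asymmetric unit.
#' @param provenance optional experimental form name or candidate tag.
#' @return An object of class `crystal_structure`.
#' @export
crystal_structure <- function(id, cell, ops, sites, z_total = NULL,
                              z_prime = NULL, provenance = NULL) {
  stopifnot(inherits(cell, "unit_cell"))
  if (!length(ops)) ops <- list(identity_symop())
  is_id <- vapply(ops, function(o) {
    max(abs(o$rotation - diag(3))) < 1e-9 && max(abs(o$translation %% 1)) < 1e-9
  }, logical(1))
  if (any(is_id)) {
    ops <- c(ops[which(is_id)[1]], ops[!seq_along(ops) %in% which(is_id)[1]])
  } else {
    ops <- c(list(identity_symop()), ops)
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("label", "element", "fx", "fy", "fz")
  if (!all(need %in% names(sites))) {
    ps_format_error("sites must have columns label, element, fx, fy, fz")
  }
  if (anyDuplicated(sites$label)) ps_format_error("site labels must be unique")
  check_elements(sites$element)
  for (col in c("fx", "fy", "fz")) {
    sites[[col]] <- sites[[col]] - floor(sites[[col]])
  }
  structure(list(id = as.character(id), cell = cell, ops = ops,
                 sites = sites, z_total = z_total, z_prime = z_prime,
                 provenance = provenance),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("crystal structure '%s': %d asymmetric site(s), %d symmetry op(s)\n",
              x$id, nrow(x$sites), length(x$ops)))
  print(x$cell)
  if (!is.null(x$z_total)) cat(sprintf("Z = %d, Z' = %s\n", x$z_total,
                                       format(x$z_prime %||% NA)))
  if (!is.null(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

.strip_esd <- function(x) as.numeric(sub("\\(.*\\)", "", x))

.cif_tokens <- function(line) {
  # whitespace-split respecting single/double quotes
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

#' Read a crystal structure from CIF
#'
#' Supports cell parameters, explicit `_symmetry_equiv_pos_as_xyz` /
#' `_space_group_symop_operation_xyz` loops (preferred) or a Hermann-Mauguin
#' symbol resolved through a bundled table, and fractional atom sites.
#'
#' @param path path to a CIF file.
#' @return A [crystal_structure()] with the identity operation first and
#'   fractional coordinates reduced to `[0, 1)`.
#' @export
read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  id <- tools::file_path_sans_ext(basename(path))
  scalars <- list()
  loops <- list()

  i <- 1
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (grepl("^data_", ln)) {
      id <- sub("^data_", "", ln)
      i <- i + 1
    } else if (tolower(ln) == "loop_") {
      i <- i + 1
      tags <- character(0)
      while (i <= n && startsWith(lines[i], "_")) {
        tags <- c(tags, tolower(.cif_tokens(lines[i])[1]))
        i <- i + 1
      }
      rows <- list()
      while (i <= n && !startsWith(lines[i], "_") &&
             !grepl("^(loop_|data_)", lines[i], ignore.case = TRUE)) {
        toks <- .cif_tokens(lines[i])
        if (length(toks)) rows[[length(rows) + 1]] <- toks
        i <- i + 1
      }
      if (length(rows)) {
        ok <- vapply(rows, length, integer(1)) == length(tags)
        if (!all(ok)) ps_format_error("CIF loop row/column mismatch")
        m <- do.call(rbind, rows)
        colnames(m) <- tags
        loops[[length(loops) + 1]] <- as.data.frame(m, stringsAsFactors = FALSE)
      }
    } else if (startsWith(ln, "_")) {
      toks <- .cif_tokens(ln)
      if (length(toks) >= 2) {
        scalars[[tolower(toks[1])]] <- paste(toks[-1], collapse = " ")
      }
      i <- i + 1
    } else {
      i <- i + 1
    }
  }

  cell_tags <- paste0("_cell_length_", c("a", "b", "c"))
  ang_tags <- paste0("_cell_angle_", c("alpha", "beta", "gamma"))
  if (!all(c(cell_tags, ang_tags) %in% names(scalars))) {
    ps_format_error("CIF is missing cell parameters")
  }
  cell <- unit_cell(.strip_esd(scalars[[cell_tags[1]]]),
                    .strip_esd(scalars[[cell_tags[2]]]),
                    .strip_esd(scalars[[cell_tags[3]]]),
                    .strip_esd(scalars[[ang_tags[1]]]),
                    .strip_esd(scalars[[ang_tags[2]]]),
                    .strip_esd(scalars[[ang_tags[3]]]))

  symop_tags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  ops <- NULL
  for (lp in loops) {
    hit <- intersect(symop_tags, names(lp))
    if (length(hit)) {
      ops <- lapply(lp[[hit[1]]], parse_symop)
      break
    }
  }
  if (is.null(ops)) {
    for (tag in symop_tags) {
      if (tag %in% names(scalars)) ops <- list(parse_symop(scalars[[tag]]))
    }
  }
  if (is.null(ops)) {
    hm_tags <- c("_symmetry_space_group_name_h-m", "_space_group_name_h-m_alt")
    hm <- NULL
    for (tag in hm_tags) if (tag %in% names(scalars)) hm <- scalars[[tag]]
    if (is.null(hm)) {
      ps_symmetry_error("CIF has neither symmetry operations nor a space-group symbol")
    }
    ops <- spacegroup_ops(hm)
  }

  atom_loop <- NULL
  for (lp in loops) {
    if (all(c("_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z")
            %in% names(lp))) {
      atom_loop <- lp
      break
    }
  }
  if (is.null(atom_loop) || !nrow(atom_loop)) {
    ps_format_error("CIF has no atom site loop")
  }
  label <- atom_loop[["_atom_site_label"]] %||%
    paste0("X", seq_len(nrow(atom_loop)))
  element <- atom_loop[["_atom_site_type_symbol"]]
  if (is.null(element)) {
    element <- sub("^([A-Z][a-z]?).*$", "\\1", label)
  }
  element <- sub("[0-9+-].*$", "", element)
  check_elements(element)
  occ <- atom_loop[["_atom_site_occupancy"]]
  if (!is.null(occ)) {
    occ_v <- .strip_esd(occ)
    if (any(abs(occ_v - 1) > 1e-6)) {
      ps_format_error("partial occupancies are not supported (disordered structure)")
    }
  }
  sites <- data.frame(
    label = label,
    element = element,
    fx = .strip_esd(atom_loop[["_atom_site_fract_x"]]),
    fy = .strip_esd(atom_loop[["_atom_site_fract_y"]]),
    fz = .strip_esd(atom_loop[["_atom_site_fract_z"]]),
    stringsAsFactors = FALSE
  )
  crystal_structure(id = id, cell = cell, ops = ops, sites = sites)
}

#' Write a crystal structure to CIF
#'
#' The emitted file round-trips through [read_cif()] losslessly to 1e-6 in
#' fractional coordinates and 1e-4 in cell parameters.
#'
#' @param structure a [crystal_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(structure, path) {
  stopifnot(inherits(structure, "crystal_structure"))
  if (!nrow(structure$sites)) ps_format_error("structure has no atom sites")
  cell <- structure$cell
  out <- c(
    paste0("data_", gsub("\\s", "_", structure$id)),
    sprintf("_cell_length_a %.6f", cell$a),
    sprintf("_cell_length_b %.6f", cell$b),
    sprintf("_cell_length_c %.6f", cell$c),
    sprintf("_cell_angle_alpha %.6f", cell$alpha),
    sprintf("_cell_angle_beta %.6f", cell$beta),
    sprintf("_cell_angle_gamma %.6f", cell$gamma),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    vapply(structure$ops, function(o) paste0("'", symop_to_xyz(o), "'"),
           character(1)),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    sprintf("%s %s %.8f %.8f %.8f",
            structure$sites$label, structure$sites$element,
            structure$sites$fx, structure$sites$fy, structure$sites$fz)
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Export a structure's expanded unit cell as extended XYZ
#'
#' Debugging aid: one frame with Cartesian coordinates of every symmetry copy.
#'
#' @param structure a [crystal_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path) {
  ex <- expand_sites(structure)
  cart <- frac_to_cart(as.matrix(ex[, c("fx", "fy", "fz")]), structure$cell)
  m <- cell_matrix(structure$cell)
  lattice <- paste(sprintf("%.6f", as.numeric(m)), collapse = " ")
  out <- c(
    nrow(ex),
    sprintf('Lattice="%s" Properties=species:S:1:pos:R:3', lattice),
    sprintf("%s %.6f %.6f %.6f", ex$element, cart[, 1], cart[, 2], cart[, 3])
  )
  writeLines(out, path)
  invisible(path)
}
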