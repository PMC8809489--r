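# Molecule perception: symmetry expansion, covalent-radius bond perception
# under the minimum-image convention, and extraction of whole molecules
# unwrapped across periodic boundaries.

#' Expand asymmetric-unit sites by all symmetry operations
#'
#' @param structure a [crystal_structure()].
#' @param dedup_tol atoms generated closer than this (Angstrom) are treated as
#'   the same site (special positions) and collapsed.
#' @return Data frame with columns `element`, `label`, `fx`, `fy`, `fz`,
#'   `site_index` (row in the asymmetric unit) and `op_index`.
#' @export
expand_sites <- function(structure, dedup_tol = 0.1) {
  stopifnot(inherits(structure, "crystal_structure"))
  s <- structure$sites
  frac <- as.matrix(s[, c("fx", "fy", "fz")])
  pieces <- lapply(seq_along(structure$ops), function(k) {
    f <- apply_symop(structure$ops[[k]], frac, reduce = TRUE)
    data.frame(element = s$element, label = s$label,
               fx = f[, 1], fy = f[, 2], fz = f[, 3],
               site_index = seq_len(nrow(s)), op_index = k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  # collapse coincident images (special positions)
  if (nrow(out) > 1) {
    cart <- frac_to_cart(as.matrix(out[, c("fx", "fy", "fz")]), structure$cell)
    keep <- rep(TRUE, nrow(out))
    d <- .min_image_dist(cart, structure$cell)
    dup <- which(d < dedup_tol & upper.tri(d), arr.ind = TRUE)
    if (nrow(dup)) keep[dup[, 2]] <- FALSE
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# full pairwise minimum-image distance matrix (Cartesian input)
.min_image_dist <- function(cart, cell) {
  frac <- cart_to_frac(cart, cell)
  m <- cell_matrix(cell)
  n <- nrow(frac)
  d <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(frac[, k], frac[, k], `-`)
    dk <- dk - round(dk)
    assign(paste0("f", k), dk)
  }
  dx <- m[1, 1] * f1 + m[1, 2] * f2 + m[1, 3] * f3
  dy <- m[2, 1] * f1 + m[2, 2] * f2 + m[2, 3] * f3
  dz <- m[3, 1] * f1 + m[3, 2] * f2 + m[3, 3] * f3
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Perceive covalent bonds under the minimum-image convention
#'
#' Two atoms are bonded when their minimum-image distance does not exceed
#' `tolerance` times the sum of their covalent radii. Hydrogens keep only the
#' bond to their nearest heavy atom.
#'
#' @param coords n x 3 Cartesian coordinates (Angstrom).
#' @param elements character vector of element symbols (length n).
#' @param cell a [unit_cell()]; when `NULL`, plain (non-periodic) distances
#'   are used.
#' @param tolerance unitless scale on covalent-radius sums (default 1.2).
#' @return Two-column integer matrix of bonded atom index pairs (i < j).
#' @export
perceive_bonds <- function(coords, elements, cell = NULL, tolerance = 1.2) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  check_elements(elements)
  if (n < 2) return(matrix(integer(0), 0, 2))
  d <- if (is.null(cell)) {
    as.matrix(stats::dist(coords))
  } else {
    .min_image_dist(coords, cell)
  }
  r <- covalent_radius(elements)
  cutoff <- outer(r, r, `+`) * tolerance
  adj <- d <= cutoff & d > 0.1
  # hydrogens: keep only the nearest heavy-atom bond
  hyd <- which(elements == "H")
  for (h in hyd) {
    partners <- which(adj[h, ])
    heavy <- partners[elements[partners] != "H"]
    if (length(heavy) > 1) {
      keep <- heavy[which.min(d[h, heavy])]
      drop <- setdiff(partners, keep)
      adj[h, drop] <- FALSE
      adj[drop, h] <- FALSE
    } else if (length(heavy) == 1) {
      drop <- setdiff(partners, heavy)
      adj[h, drop] <- FALSE
      adj[drop, h] <- FALSE
    }
  }
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  colnames(idx) <- NULL
  unname(idx[order(idx[, 1], idx[, 2]), , drop = FALSE])
}

#' Extract whole molecules from a crystal structure
#'
#' Expands the asymmetric unit by all symmetry operations, perceives bonds
#' under the minimum-image convention, and unwraps each connected component by
#' breadth-first traversal with minimum-image shifts so that no bond crosses a
#' cell boundary.
#'
#' @param structure a [crystal_structure()].
#' @param tolerance bond-perception tolerance (see [perceive_bonds()]).
#' @return List of molecule objects, each with `elements`, `labels`, `coords`
#'   (Cartesian, unwrapped), `frac` (unwrapped fractional), `bonds`,
#'   `centroid`, `site_index` and `op_index`. Atoms are ordered by
#'   asymmetric-unit site index.
#' @export
extract_molecules <- function(structure, tolerance = 1.2) {
  ex <- expand_sites(structure)
  frac <- as.matrix(ex[, c("fx", "fy", "fz")])
  cart <- frac_to_cart(frac, structure$cell)
  bonds <- perceive_bonds(cart, ex$element, structure$cell, tolerance)
  n <- nrow(ex)
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  comp <- rep(NA_integer_, n)
  ufrac <- frac
  ncomp <- 0
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    ncomp <- ncomp + 1
    comp[start] <- ncomp
    queue <- start
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (is.na(comp[nb])) {
          comp[nb] <- ncomp
          # minimum-image unwrap relative to current atom
          ufrac[nb, ] <- frac[nb, ] - round(frac[nb, ] - ufrac[cur, ])
          queue <- c(queue, nb)
        }
      }
    }
  }
  if (!is.null(structure$z_total) && ncomp != structure$z_total) {
    ps_connectivity_error(sprintf(
      "expected %d molecules (z_total) but connectivity yields %d",
      structure$z_total, ncomp))
  }
  m <- cell_matrix(structure$cell)
  mols <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    idx <- which(comp == k)
    idx <- idx[order(ex$site_index[idx])]
    uf <- ufrac[idx, , drop = FALSE]
    cc <- t(m %*% t(uf))
    bsub <- bonds[bonds[, 1] %in% idx & bonds[, 2] %in% idx, , drop = FALSE]
    remap <- match(bsub, idx)
    bsub <- matrix(remap, ncol = 2)
    mols[[k]] <- structure(list(
      atom_indices = idx,
      elements = ex$element[idx],
      labels = ex$label[idx],
      coords = cc,
      frac = uf,
      bonds = bsub,
      centroid = colMeans(cc),
      site_index = ex$site_index[idx],
      op_index = ex$op_index[idx][1]
    ), class = "molecule")
  }
  mols
}

#' Build a molecule object from bare coordinates
#'
#' Convenience constructor for gas-phase molecules (no cell): bonds are
#' perceived with plain distances.
#'
#' @param elements character vector of element symbols.
#' @param coords n x 3 Cartesian coordinates (Angstrom).
#' @param labels optional atom labels.
#' @param tolerance bond-perception tolerance.
#' @return A `molecule` object.
#' @export
molecule <- function(elements, coords, labels = NULL, tolerance = 1.2) {
  coords <- as.matrix(coords)
  check_elements(elements)
  if (is.null(labels)) labels <- paste0(elements, seq_along(elements))
  bonds <- perceive_bonds(coords, elements, cell = NULL, tolerance = tolerance)
  structure(list(atom_indices = seq_along(elements), elements = elements,
                 labels = labels, coords = coords, frac = NULL, bonds = bonds,
                 centroid = colMeans(coords), site_index = seq_along(elements),
                 op_index = 1L),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms (%s), %d bonds\n", length(x$elements),
              paste(rle(sort(x$elements))$values, collapse = ""),
              nrow(x$bonds)))
  invisible(x)
}

#' Detect Z and Z' of a structure
#'
#' `z_total` is the number of whole molecules in the expanded unit cell;
#' `z_prime = z_total / number of symmetry operations` is the number of
#' symmetry-distinct molecules in the asymmetric unit.
#'
#' @param structure a [crystal_structure()].
#' @param tolerance bond-perception tolerance.
#' @return List with elements `z_total` and `z_prime`.
#' @export
detect_zprime <- function(structure, tolerance = 1.2) {
  s <- structure
  s$z_total <- NULL
  mols <- extract_molecules(s, tolerance)
  z_total <- length(mols)
  nops <- length(structure$ops)
  if (z_total %% nops != 0) {
    ps_connectivity_error(
      "molecule count is not a multiple of the symmetry-operation count")
  }
  list(z_total = z_total, z_prime = z_total %/% nops)
}

#' Molar mass of the molecules in a structure
#'
#' @param structure a [crystal_structure()].
#' @param tolerance bond-perception tolerance.
#' @return Molar mass in g/mol of one molecule (total cell mass / Z).
#' @export
molar_mass <- function(structure, tolerance = 1.2) {
  z <- structure$z_total %||% detect_zprime(structure, tolerance)$z_total
  sum(atomic_mass(structure$sites$element)) * length(structure$ops) / z
}

#' Expand a structure to a P1 supercell
#'
#' All symmetry copies and lattice translations become explicit sites of a
#' larger triclinic cell with only the identity operation.
#'
#' @param structure a [crystal_structure()].
#' @param n integer 3-vector of repeats along a, b, c.
#' @return A [crystal_structure()] in P1.
#' @export
make_p1_supercell <- function(structure, n = c(2, 2, 2)) {
  stopifnot(length(n) == 3, all(n >= 1))
  ex <- expand_sites(structure)
  cell <- structure$cell
  newcell <- unit_cell(cell$a * n[1], cell$b * n[2], cell$c * n[3],
                       cell$alpha, cell$beta, cell$gamma)
  shifts <- expand.grid(i = 0:(n[1] - 1), j = 0:(n[2] - 1), k = 0:(n[3] - 1))
  pieces <- lapply(seq_len(nrow(shifts)), function(r) {
    data.frame(
      element = ex$element,
      fx = (ex$fx + shifts$i[r]) / n[1],
      fy = (ex$fy + shifts$j[r]) / n[2],
      fz = (ex$fz + shifts$k[r]) / n[3],
      stringsAsFactors = FALSE
    )
  })
  sites <- do.call(rbind, pieces)
  sites$label <- paste0(sites$element, seq_len(nrow(sites)))
  z <- if (!is.null(structure$z_total)) structure$z_total * prod(n) else NULL
  crystal_structure(paste0(structure$id, "_super"), newcell,
                    list(identity_symop()), sites,
                    z_total = z, z_prime = z,
                    provenance = structure$provenance)
}
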