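# Packing-similarity comparison via N-molecule cluster RMSD: build an
# n-molecule cluster around a central molecule in each structure, pair
# molecules between the clusters, and superpose the paired non-hydrogen atoms
# by least squares.

# all molecules of the unit cell replicated over lattice translations
.supercell_molecules <- function(structure, range = 2, tolerance = 1.2) {
  mols <- extract_molecules(structure, tolerance)
  m <- cell_matrix(structure$cell)
  shifts <- as.matrix(expand.grid(i = -range:range, j = -range:range,
                                  k = -range:range))
  trans <- shifts %*% t(m)
  base_centroids <- t(vapply(mols, function(x) x$centroid, numeric(3)))
  n_m <- length(mols)
  n_s <- nrow(shifts)
  centroids <- matrix(0, n_m * n_s, 3)
  mol_id <- integer(n_m * n_s)
  shift_id <- integer(n_m * n_s)
  r <- 1
  for (s in seq_len(n_s)) {
    idx <- r:(r + n_m - 1)
    centroids[idx, ] <- sweep(base_centroids, 2, trans[s, ], `+`)
    mol_id[idx] <- seq_len(n_m)
    shift_id[idx] <- s
    r <- r + n_m
  }
  list(mols = mols, centroids = centroids, mol_id = mol_id,
       trans = trans, shift_id = shift_id,
       zero_shift = which(rowSums(abs(shifts)) == 0)[1],
       cell_center = as.numeric(m %*% c(0.5, 0.5, 0.5)))
}

.copy_coords <- function(env, copy_idx, heavy_only = TRUE) {
  mol <- env$mols[[env$mol_id[copy_idx]]]
  coords <- sweep(mol$coords, 2, env$trans[env$shift_id[copy_idx], ], `+`)
  if (heavy_only) coords <- coords[mol$elements != "H", , drop = FALSE]
  coords
}

.copy_elements <- function(env, copy_idx, heavy_only = TRUE) {
  el <- env$mols[[env$mol_id[copy_idx]]]$elements
  if (heavy_only) el <- el[el != "H"]
  el
}

# indices (into env$centroids) of the n cluster molecules around copy `center`
.cluster_indices <- function(env, center, n) {
  d <- sqrt(rowSums(sweep(env$centroids, 2, env$centroids[center, ])^2))
  order(d)[seq_len(n)]
}

#' N-molecule cluster RMSD between two crystal structures
#'
#' Builds an n-molecule cluster in each structure (a central molecule plus the
#' n-1 nearest by centroid distance, using periodic images), pairs cluster
#' molecules between the structures, and superposes the paired non-hydrogen
#' atoms by a least-squares rotation. The central molecule of the first
#' structure is the one nearest the cell centroid; every symmetry-distinct
#' molecule of the second structure is tried as the matching center (up to
#' `max_centers`, nearest the cell interior first) and the best result kept.
#' If `allow_inversion` is `TRUE` the mirror image of the second cluster is
#' also tried.
#'
#' @param a,b [crystal_structure()]s containing the same molecule.
#' @param n cluster size in molecules (default 15).
#' @param distance_tol fraction of the nearest-neighbour centroid spacing
#'   within which two superposed molecule centroids count as paired.
#' @param allow_inversion also try the enantiomorph of `b`.
#' @param tolerance bond-perception tolerance.
#' @param max_centers cap on candidate central molecules in `b`.
#' @return A `match_result`: list with `n_matched`, `rmsd` (Angstrom, over
#'   matched non-hydrogen atoms), `success` (`n_matched == n`) and `inverted`.
#' @export
rmsd_n_cluster <- function(a, b, n = 15, distance_tol = 0.25,
                           allow_inversion = TRUE, tolerance = 1.2,
                           max_centers = 12) {
  env_a <- .supercell_molecules(a, tolerance = tolerance)
  env_b <- .supercell_molecules(b, tolerance = tolerance)
  .rmsd_n_cluster_env(env_a, env_b, n = n, distance_tol = distance_tol,
                      allow_inversion = allow_inversion,
                      max_centers = max_centers)
}

.rmsd_n_cluster_env <- function(env_a, env_b, n, distance_tol = 0.25,
                                allow_inversion = TRUE, max_centers = 12) {
  n_avail <- min(nrow(env_a$centroids), nrow(env_b$centroids))
  if (n > n_avail) {
    ps_value_error(sprintf("cluster size %d exceeds the %d molecules available",
                           n, n_avail))
  }
  # same molecule required: compare heavy-atom element multisets
  el_a <- sort(.copy_elements(env_a, 1))
  el_b <- sort(.copy_elements(env_b, 1))
  if (!identical(el_a, el_b)) {
    ps_value_error("structures do not contain the same molecule (heavy-atom mismatch)")
  }

  # cluster A around the molecule nearest the cell centroid
  in_cell_a <- which(env_a$shift_id == env_a$zero_shift)
  da <- sqrt(rowSums(sweep(env_a$centroids[in_cell_a, , drop = FALSE], 2,
                           env_a$cell_center)^2))
  center_a <- in_cell_a[which.min(da)]
  clu_a <- .cluster_indices(env_a, center_a, n)
  coords_a <- lapply(clu_a, function(i) .copy_coords(env_a, i))
  cent_a <- env_a$centroids[clu_a, , drop = FALSE]
  nn_a <- sort(sqrt(rowSums(sweep(cent_a[-1, , drop = FALSE], 2,
                                  cent_a[1, ])^2)))[1]
  pair_cut <- distance_tol * nn_a

  # candidate centers in B: unit-cell molecules nearest the cell interior
  in_cell_b <- which(env_b$shift_id == env_b$zero_shift)
  db <- sqrt(rowSums(sweep(env_b$centroids[in_cell_b, , drop = FALSE], 2,
                           env_b$cell_center)^2))
  cand <- in_cell_b[order(db)]
  if (length(cand) > max_centers) cand <- cand[seq_len(max_centers)]

  a_center_coords <- coords_a[[1]]
  best <- list(n_matched = 0L, rmsd = Inf, success = FALSE, inverted = FALSE)
  inv_opts <- if (allow_inversion) c(FALSE, TRUE) else FALSE

  for (center_b in cand) {
    # generous pool of B molecules around the candidate center
    pool <- .cluster_indices(env_b, center_b, min(3 * n, nrow(env_b$centroids)))
    pool_coords <- lapply(pool, function(i) .copy_coords(env_b, i))
    b_center0 <- env_b$centroids[center_b, ]
    for (inv in inv_opts) {
      pc <- pool_coords
      if (inv) {
        pc <- lapply(pc, function(x) sweep(-sweep(x, 2, b_center0), 2,
                                           -b_center0))
      }
      if (nrow(pc[[1]]) != nrow(a_center_coords)) next
      # orient by superposing the central molecules
      fit0 <- kabsch(a_center_coords, pc[[1]])
      moved_cent <- t(vapply(pc, function(x) {
        colMeans(apply_rigid(x, fit0$rotation, fit0$translation))
      }, numeric(3)))
      res <- .match_and_fit(coords_a, cent_a, pc, moved_cent, pair_cut,
                            fit0)
      # one refinement pass with the full-cluster fit
      if (res$n_matched >= 2) {
        moved_cent2 <- t(vapply(pc, function(x) {
          colMeans(apply_rigid(x, res$fit$rotation, res$fit$translation))
        }, numeric(3)))
        res2 <- .match_and_fit(coords_a, cent_a, pc, moved_cent2, pair_cut,
                               res$fit)
        if (res2$n_matched > res$n_matched ||
            (res2$n_matched == res$n_matched && res2$rmsd < res$rmsd)) {
          res <- res2
        }
      }
      if (res$n_matched > best$n_matched ||
          (res$n_matched == best$n_matched && res$rmsd < best$rmsd)) {
        best <- list(n_matched = res$n_matched, rmsd = res$rmsd,
                     success = res$n_matched == n, inverted = inv)
      }
    }
  }
  structure(best, class = "match_result")
}

# greedy nearest-centroid assignment, then joint least-squares fit
.match_and_fit <- function(coords_a, cent_a, pool_coords, moved_cent,
                           pair_cut, seed_fit) {
  n_a <- nrow(cent_a)
  n_b <- nrow(moved_cent)
  d <- matrix(Inf, n_a, n_b)
  for (i in seq_len(n_a)) {
    d[i, ] <- sqrt(rowSums(sweep(moved_cent, 2, cent_a[i, ])^2))
  }
  pairs <- matrix(integer(0), 0, 2)
  dd <- d
  repeat {
    k <- which.min(dd)
    if (!length(k) || !is.finite(dd[k])) break
    ij <- arrayInd(k, dim(dd))
    if (dd[k] > pair_cut) break
    pairs <- rbind(pairs, ij)
    dd[ij[1], ] <- Inf
    dd[, ij[2]] <- Inf
  }
  if (!nrow(pairs)) {
    return(list(n_matched = 0L, rmsd = Inf, fit = seed_fit))
  }
  pa <- do.call(rbind, lapply(pairs[, 1], function(i) coords_a[[i]]))
  pb <- do.call(rbind, lapply(pairs[, 2], function(j) pool_coords[[j]]))
  if (nrow(pa) != nrow(pb)) {
    return(list(n_matched = 0L, rmsd = Inf, fit = seed_fit))
  }
  fit <- kabsch(pa, pb)
  list(n_matched = nrow(pairs), rmsd = fit$rmsd, fit = fit)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("cluster match: %d molecule(s) paired, rmsd = %.4f A%s%s\n",
              x$n_matched, x$rmsd,
              if (x$success) " [success]" else " [incomplete]",
              if (isTRUE(x$inverted)) " (inverted)" else ""))
  invisible(x)
}
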