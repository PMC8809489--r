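# Ranked energy-density landscapes: construction, energy-window queries,
# packing-similarity deduplication and experimental labelling.

new_landscape <- function(df) {
  need <- c("structure_id", "rel_energy", "rank")
  if (!all(need %in% names(df))) {
    ps_value_error("landscape needs structure_id, rel_energy and rank columns")
  }
  class(df) <- c("landscape", "data.frame")
  df
}

.rerank <- function(df) {
  ord <- order(df$rel_energy, df$structure_id)
  df <- df[ord, , drop = FALSE]
  df$rel_energy <- df$rel_energy - df$rel_energy[1]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Build a ranked energy-density landscape
#'
#' Entries are ranked by per-molecule relative energy against the global
#' minimum; exact ties are broken lexicographically by structure id. Density,
#' torsion angle and color class are derived from the structures when they are
#' supplied.
#'
#' @param records list of corrected [energy_record()]s, or a named numeric
#'   vector of per-molecule energies (kJ/mol).
#' @param structures optional named list of [crystal_structure()]s matching
#'   the record ids.
#' @param spec a [dihedral_spec()] for the torsion/color columns.
#' @param tolerance bond-perception tolerance.
#' @return A `landscape` data frame with columns `structure_id`, `rel_energy`
#'   (kJ/mol per molecule, 0 at rank 1), `density` (g/cm^3 or `NA`), `theta`,
#'   `color_class`, `experimental_label` (`NA` until
#'   [label_experimental()] is used) and `rank`.
#' @export
build_landscape <- function(records, structures = NULL,
                            spec = dihedral_spec(), tolerance = 1.2) {
  e <- .per_molecule_energies(records)
  if (anyDuplicated(names(e))) ps_value_error("duplicate structure ids")
  df <- data.frame(structure_id = names(e),
                   rel_energy = unname(e - min(e)),
                   density = NA_real_, theta = NA_real_,
                   color_class = NA_character_,
                   experimental_label = NA_character_,
                   rank = NA_integer_,
                   stringsAsFactors = FALSE)
  if (!is.null(structures)) {
    for (i in seq_len(nrow(df))) {
      st <- structures[[df$structure_id[i]]]
      if (is.null(st)) next
      df$density[i] <- density(st)
      mols <- extract_molecules(st, tolerance)
      th <- tryCatch(measure_dihedral(mols[[1]], spec), polyscape_error = function(e) NA_real_)
      df$theta[i] <- th
      if (!is.na(th)) df$color_class[i] <- classify_color(th)
    }
  }
  new_landscape(.rerank(df))
}

#' Count landscape entries inside an energy window
#'
#' @param landscape a landscape from [build_landscape()].
#' @param window energy window in kJ/mol per molecule; entries with
#'   `rel_energy <= window` are counted (boundary inclusive).
#' @param predicate optional filter: a function taking the landscape data
#'   frame and returning a logical vector, or a character experimental label
#'   (`NA`-safe equality on `experimental_label`).
#' @return Integer count.
#' @export
count_in_window <- function(landscape, window, predicate = NULL) {
  stopifnot(inherits(landscape, "landscape"))
  if (length(window) != 1 || is.na(window) || window < 0) {
    ps_value_error("window must be a single value >= 0")
  }
  keep <- landscape$rel_energy <= window
  if (!is.null(predicate)) {
    sel <- if (is.function(predicate)) {
      predicate(landscape)
    } else {
      !is.na(landscape$experimental_label) &
        landscape$experimental_label == predicate
    }
    keep <- keep & sel
  }
  sum(keep)
}

#' Merge duplicate structures on a landscape
#'
#' Two entries are duplicates when their per-molecule energies differ by at
#' most `energy_tol` AND their packing matches: [rmsd_n_cluster()] pairs all
#' `n` molecules with RMSD at most `rmsd_tol`. Duplicate groups are merged
#' keeping the lowest-energy member (ties broken lexicographically); ranks are
#' recomputed. A second pass over the result merges nothing (idempotent).
#'
#' @param landscape a landscape from [build_landscape()].
#' @param structures named list of [crystal_structure()]s for all entries.
#' @param rmsd_tol RMSD threshold in Angstrom (default 0.3).
#' @param energy_tol per-molecule energy threshold in kJ/mol (default 0.5).
#' @param n cluster size for the RMSD comparison (default 15).
#' @param distance_tol,allow_inversion,tolerance passed to [rmsd_n_cluster()].
#' @return List with `landscape` (reduced, re-ranked) and `merges` (data frame
#'   of `kept`, `removed`, `rmsd`, `delta_e`, one row per collapsed entry).
#' @export
deduplicate <- function(landscape, structures, rmsd_tol = 0.3,
                        energy_tol = 0.5, n = 15, distance_tol = 0.25,
                        allow_inversion = TRUE, tolerance = 1.2) {
  stopifnot(inherits(landscape, "landscape"))
  ids <- landscape$structure_id
  missing <- setdiff(ids, names(structures))
  if (length(missing)) {
    ps_value_error(paste0("structures missing for: ",
                          paste(utils::head(missing, 5), collapse = ", ")))
  }
  envs <- new.env(parent = emptyenv())
  get_env <- function(id) {
    if (is.null(envs[[id]])) {
      envs[[id]] <- .supercell_molecules(structures[[id]], tolerance = tolerance)
    }
    envs[[id]]
  }
  # union-find over entries
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  merges <- data.frame(kept = character(0), removed = character(0),
                       rmsd = numeric(0), delta_e = numeric(0),
                       stringsAsFactors = FALSE)
  e <- landscape$rel_energy
  ord <- order(e, ids)
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    jj <- ii + 1
    while (jj <= length(ord)) {
      j <- ord[jj]
      de <- e[j] - e[i]
      if (de > energy_tol) break
      if (find(i) != find(j)) {
        res <- tryCatch(
          .rmsd_n_cluster_env(get_env(ids[i]), get_env(ids[j]), n = n,
                              distance_tol = distance_tol,
                              allow_inversion = allow_inversion),
          polyscape_error = function(err) list(success = FALSE, rmsd = Inf))
        if (isTRUE(res$success) && res$rmsd <= rmsd_tol) {
          # keep the lower-energy member (i precedes j in the energy order)
          parent[find(j)] <- find(i)
          merges <- rbind(merges, data.frame(
            kept = ids[i], removed = ids[j], rmsd = res$rmsd, delta_e = de,
            stringsAsFactors = FALSE))
        }
      }
      jj <- jj + 1
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  keep <- which(roots == seq_along(ids))
  reduced <- landscape[keep, , drop = FALSE]
  list(landscape = new_landscape(.rerank(as.data.frame(reduced))),
       merges = merges)
}

#' Label landscape entries with experimental forms
#'
#' Each reference structure labels at most one candidate (its best RMSD match
#' under the tolerance) and each candidate receives at most one label;
#' assignment is greedy by ascending RMSD. Unmatched references are reported
#' in the `unmatched` attribute.
#'
#' @param landscape a landscape from [build_landscape()].
#' @param structures named list of candidate [crystal_structure()]s.
#' @param references named list of experimental [crystal_structure()]s; names
#'   are the form labels.
#' @param rmsd_tol RMSD threshold in Angstrom.
#' @param n cluster size for the comparison.
#' @param distance_tol,allow_inversion,tolerance passed to [rmsd_n_cluster()].
#' @return The landscape with `experimental_label` filled in; attribute
#'   `unmatched` lists reference names that matched nothing.
#' @export
label_experimental <- function(landscape, structures, references,
                               rmsd_tol = 0.3, n = 15, distance_tol = 0.25,
                               allow_inversion = TRUE, tolerance = 1.2) {
  stopifnot(inherits(landscape, "landscape"))
  ids <- landscape$structure_id
  cand_envs <- lapply(structures[ids], .supercell_molecules,
                      tolerance = tolerance)
  hits <- data.frame(ref = character(0), cand = character(0),
                     rmsd = numeric(0), stringsAsFactors = FALSE)
  for (ref_name in names(references)) {
    env_r <- .supercell_molecules(references[[ref_name]],
                                  tolerance = tolerance)
    for (id in ids) {
      res <- tryCatch(
        .rmsd_n_cluster_env(env_r, cand_envs[[id]], n = n,
                            distance_tol = distance_tol,
                            allow_inversion = allow_inversion),
        polyscape_error = function(err) list(success = FALSE, rmsd = Inf))
      if (isTRUE(res$success) && res$rmsd <= rmsd_tol) {
        hits <- rbind(hits, data.frame(ref = ref_name, cand = id,
                                       rmsd = res$rmsd,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  hits <- hits[order(hits$rmsd), , drop = FALSE]
  used_ref <- character(0)
  used_cand <- character(0)
  for (k in seq_len(nrow(hits))) {
    if (hits$ref[k] %in% used_ref || hits$cand[k] %in% used_cand) next
    landscape$experimental_label[landscape$structure_id == hits$cand[k]] <-
      hits$ref[k]
    used_ref <- c(used_ref, hits$ref[k])
    used_cand <- c(used_cand, hits$cand[k])
  }
  attr(landscape, "unmatched") <- setdiff(names(references), used_ref)
  landscape
}

#' Write a landscape to CSV
#'
#' @param landscape a landscape data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(landscape, path) {
  utils::write.csv(as.data.frame(landscape), path, row.names = FALSE)
  invisible(path)
}
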