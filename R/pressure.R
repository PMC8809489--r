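# Pressure-dependent polymorph stability: H = E_latt + P*V per molecule,
# neglecting phonon/finite-temperature contributions. Energies in kJ/mol,
# volumes in A^3 and pressures in GPa, so the PV term carries the Avogadro
# conversion 0.602214076 kJ/mol per GPa*A^3. Enthalpy-vs-pressure curves are
# interpolated with a shape-preserving monotone piecewise cubic (Fritsch-
# Carlson), which cannot ring between samples, and extrapolation beyond 5% of
# the sampled pressure range is refused.

#' Enthalpy of a (P, E, V) point
#'
#' `H = E + P * V * 0.602214076` with P in GPa, V in A^3 per molecule and E,
#' H in kJ/mol per molecule.
#'
#' @param pressure pressure(s) in GPa.
#' @param energy lattice energy in kJ/mol per molecule.
#' @param volume volume in A^3 per molecule.
#' @return Enthalpy in kJ/mol per molecule (vectorised).
#' @export
enthalpy <- function(pressure, energy, volume) {
  if (any(volume <= 0)) ps_value_error("volumes must be > 0")
  if (any(pressure < 0)) ps_value_error("pressures must be >= 0")
  energy + pressure * volume * GPA_A3_TO_KJMOL
}

#' Construct a pressure-energy-volume series for one structure
#'
#' @param structure_id structure identifier.
#' @param pressure pressures in GPa (must be unique; sorted on construction).
#' @param energy lattice energies in kJ/mol per molecule.
#' @param volume volumes in A^3 per molecule.
#' @return An object of class `pv_series` (data frame with an `id` attribute,
#'   plus a derived `enthalpy` column). Volumes that increase with pressure
#'   trigger a warning, not an error.
#' @export
pv_series <- function(structure_id, pressure, energy, volume) {
  if (anyDuplicated(pressure)) ps_value_error("pressures must be unique")
  ord <- order(pressure)
  df <- data.frame(pressure = pressure[ord], energy = energy[ord],
                   volume = volume[ord])
  if (any(df$volume <= 0)) ps_value_error("volumes must be > 0")
  if (any(df$pressure < 0)) ps_value_error("pressures must be >= 0")
  if (nrow(df) >= 2 && any(diff(df$volume) > 0)) {
    warning("volumes increase with pressure in series '", structure_id, "'")
  }
  df$enthalpy <- enthalpy(df$pressure, df$energy, df$volume)
  structure(df, id = as.character(structure_id),
            class = c("pv_series", "data.frame"))
}

# monotone piecewise-cubic H(P) interpolant with coverage bookkeeping
.enthalpy_fun <- function(series) {
  if (nrow(series) < 2) {
    ps_value_error("at least two pressure points are needed for interpolation")
  }
  f <- stats::splinefun(series$pressure, series$enthalpy, method = "monoH.FC")
  attr(f, "range") <- range(series$pressure)
  f
}

.check_coverage <- function(series, pressures, slack = 0.05) {
  rng <- range(series$pressure)
  span <- diff(rng)
  lo <- rng[1] - slack * span
  hi <- rng[2] + slack * span
  if (any(pressures < lo) || any(pressures > hi)) {
    ps_coverage_error(sprintf(
      "series '%s' covers %.4g-%.4g GPa; requested grid extrapolates beyond 5%% of that range",
      attr(series, "id") %||% "?", rng[1], rng[2]))
  }
}

#' Relative enthalpy curve between two structures
#'
#' `dH(P) = H_series(P) - H_reference(P)`, each enthalpy interpolated over
#' pressure with a shape-preserving monotone piecewise cubic.
#'
#' @param series,reference [pv_series()] objects.
#' @param pressures pressure grid in GPa; must lie within the sampled range of
#'   both series (at most 5% extrapolation).
#' @return Data frame of class `delta_h_curve` with columns `pressure` and
#'   `delta_h` (kJ/mol per molecule).
#' @export
relative_enthalpy_curve <- function(series, reference, pressures) {
  stopifnot(inherits(series, "pv_series"), inherits(reference, "pv_series"))
  .check_coverage(series, pressures)
  .check_coverage(reference, pressures)
  fs <- .enthalpy_fun(series)
  fr <- .enthalpy_fun(reference)
  out <- data.frame(pressure = pressures,
                    delta_h = fs(pressures) - fr(pressures))
  structure(out, id = attr(series, "id"), reference = attr(reference, "id"),
            class = c("delta_h_curve", "data.frame"))
}

#' Locate enthalpy crossover pressures
#'
#' Finds every sign change of a sampled `dH(P)` curve by bracketing on the
#' samples and bisecting the monotone piecewise-cubic interpolant to 1e-4 GPa.
#'
#' @param delta_curve data frame with columns `pressure` and `delta_h`
#'   (e.g. from [relative_enthalpy_curve()]).
#' @param tol root tolerance in GPa.
#' @return Ascending numeric vector of crossover pressures (GPa); empty when
#'   the curve does not change sign.
#' @export
crossover_pressure <- function(delta_curve, tol = 1e-4) {
  p <- delta_curve$pressure
  h <- delta_curve$delta_h
  if (length(p) < 2) return(numeric(0))
  ord <- order(p)
  p <- p[ord]
  h <- h[ord]
  f <- stats::splinefun(p, h, method = "monoH.FC")
  .sign_change_roots(p, h, f, tol)
}

# roots of a sampled curve: genuine sign changes between consecutive nonzero
# samples (touching or identically-zero stretches are not crossings)
.sign_change_roots <- function(p, h, f, tol = 1e-4) {
  nz <- which(h != 0)
  if (length(nz) < 2) return(numeric(0))
  roots <- numeric(0)
  for (k in seq_len(length(nz) - 1)) {
    i <- nz[k]
    j <- nz[k + 1]
    if (sign(h[i]) * sign(h[j]) < 0) {
      if (j == i + 1) {
        roots <- c(roots, stats::uniroot(f, c(p[i], p[j]), tol = tol)$root)
      } else {
        # the curve is exactly zero on the samples between i and j
        roots <- c(roots, mean(p[(i + 1):(j - 1)]))
      }
    }
  }
  sort(unique(roots))
}

#' Third-order Birch-Murnaghan energy
#'
#' @param volume volumes in A^3 per molecule.
#' @param e0 minimum energy (kJ/mol per molecule).
#' @param v0 equilibrium volume (A^3).
#' @param b0 bulk modulus (GPa).
#' @param b0p pressure derivative of the bulk modulus (unitless).
#' @return Energies in kJ/mol per molecule.
#' @export
birch_murnaghan_energy <- function(volume, e0, v0, b0, b0p) {
  eta <- (v0 / volume)^(2 / 3)
  e0 + 9 * v0 * b0 * GPA_A3_TO_KJMOL / 16 *
    ((eta - 1)^3 * b0p + (eta - 1)^2 * (6 - 4 * eta))
}

#' Third-order Birch-Murnaghan pressure
#'
#' @inheritParams birch_murnaghan_energy
#' @return Pressures in GPa.
#' @export
birch_murnaghan_pressure <- function(volume, v0, b0, b0p) {
  x <- (v0 / volume)
  3 * b0 / 2 * (x^(7 / 3) - x^(5 / 3)) * (1 + 0.75 * (b0p - 4) * (x^(2 / 3) - 1))
}

#' Construct Birch-Murnaghan parameters
#'
#' @param e0 minimum energy (kJ/mol per molecule).
#' @param v0 equilibrium volume (A^3 per molecule, > 0).
#' @param b0 bulk modulus (GPa, > 0).
#' @param b0p pressure derivative of the bulk modulus.
#' @return An object of class `eos_params`.
#' @export
eos_params <- function(e0, v0, b0, b0p = 4) {
  if (v0 <= 0) ps_value_error("V0 must be > 0")
  if (b0 <= 0) ps_value_error("B0 must be > 0")
  structure(list(e0 = e0, v0 = v0, b0 = b0, b0p = b0p), class = "eos_params")
}

#' Volume of an EOS phase at a given pressure
#'
#' Solves `P_BM(V) = P` by bisection to 1e-10 relative.
#'
#' @param eos an [eos_params()].
#' @param pressure pressure(s) in GPa.
#' @return Volumes in A^3 per molecule.
#' @export
eos_volume_at_pressure <- function(eos, pressure) {
  stopifnot(inherits(eos, "eos_params"))
  vapply(pressure, function(p) {
    if (abs(p) < 1e-14) return(eos$v0)
    f <- function(v) birch_murnaghan_pressure(v, eos$v0, eos$b0, eos$b0p) - p
    stats::uniroot(f, c(0.2 * eos$v0, 5 * eos$v0), tol = 1e-10 * eos$v0)$root
  }, numeric(1))
}

#' Analytic enthalpy of an EOS phase
#'
#' `H(P) = E(V(P)) + P V(P)` in kJ/mol per molecule.
#'
#' @param eos an [eos_params()].
#' @param pressure pressure(s) in GPa.
#' @return Enthalpies in kJ/mol per molecule.
#' @export
eos_enthalpy <- function(eos, pressure) {
  v <- eos_volume_at_pressure(eos, pressure)
  birch_murnaghan_energy(v, eos$e0, eos$v0, eos$b0, eos$b0p) +
    pressure * v * GPA_A3_TO_KJMOL
}

#' Fit a third-order Birch-Murnaghan equation of state
#'
#' Least squares on (V, E) samples via Levenberg-Marquardt, with curvature-
#' based starting values.
#'
#' @param volume volumes in A^3 per molecule (at least 4 samples spanning at
#'   least 10% in volume).
#' @param energy energies in kJ/mol per molecule.
#' @return An [eos_params()] with attribute `rms_residual` (kJ/mol).
#' @export
fit_eos <- function(volume, energy) {
  if (length(volume) != length(energy)) ps_value_error("length mismatch")
  if (length(volume) < 4) {
    ps_value_error("at least 4 (V, E) samples are required for a 4-parameter fit")
  }
  span <- diff(range(volume)) / stats::median(volume)
  if (span < 0.10) {
    ps_value_error("volume samples must span at least 10% of the median volume")
  }
  i0 <- which.min(energy)
  v0_start <- volume[i0]
  e0_start <- energy[i0]
  # curvature estimate from a quadratic fit: B0 = V0 * d2E/dV2 (unit-converted)
  qf <- stats::lm(energy ~ stats::poly(volume, 2, raw = TRUE))
  curv <- 2 * stats::coef(qf)[[3]]
  b0_start <- max(abs(curv) * v0_start / GPA_A3_TO_KJMOL, 1)
  df <- data.frame(v = volume, e = energy)
  fit <- minpack.lm::nlsLM(
    e ~ birch_murnaghan_energy(v, e0, v0, b0, b0p),
    data = df,
    start = list(e0 = e0_start, v0 = v0_start, b0 = b0_start, b0p = 4),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  cf <- stats::coef(fit)
  if (cf[["v0"]] <= 0 || cf[["b0"]] <= 0) {
    ps_value_error("EOS fit did not converge to a physical minimum")
  }
  out <- eos_params(cf[["e0"]], cf[["v0"]], cf[["b0"]], cf[["b0p"]])
  attr(out, "rms_residual") <- sqrt(mean(stats::residuals(fit)^2))
  out
}

#' Pressure-stability screen over a set of structures
#'
#' Interpolates every series on a common pressure grid, reports the enthalpy
#' ordering and the most stable structure at each pressure, and locates every
#' crossover of each structure against the reference.
#'
#' @param series_list named list of [pv_series()] (names are structure ids).
#' @param reference_id id of the reference structure.
#' @param pressures pressure grid in GPa.
#' @return An object of class `pressure_screen`: list with `pressures`,
#'   `enthalpy` (grid x structure matrix), `delta_h` (relative to the
#'   reference), `most_stable` (id per grid point) and `crossovers` (data
#'   frame of `structure_id`, `pressure`).
#' @export
pressure_screen <- function(series_list, reference_id, pressures) {
  ids <- names(series_list)
  if (is.null(ids)) ps_value_error("series_list must be named")
  if (!reference_id %in% ids) ps_value_error("reference series not found")
  hmat <- sapply(ids, function(id) {
    s <- series_list[[id]]
    .check_coverage(s, pressures)
    .enthalpy_fun(s)(pressures)
  })
  hmat <- matrix(hmat, nrow = length(pressures),
                 dimnames = list(NULL, ids))
  dmat <- hmat - hmat[, reference_id]
  most_stable <- ids[apply(hmat, 1, which.min)]
  cross <- data.frame(structure_id = character(0), pressure = numeric(0),
                      stringsAsFactors = FALSE)
  for (id in setdiff(ids, reference_id)) {
    r <- crossover_pressure(data.frame(pressure = pressures,
                                       delta_h = dmat[, id]))
    if (length(r)) {
      cross <- rbind(cross, data.frame(structure_id = id, pressure = r,
                                       stringsAsFactors = FALSE))
    }
  }
  structure(list(pressures = pressures, enthalpy = hmat, delta_h = dmat,
                 reference = reference_id, most_stable = most_stable,
                 crossovers = cross),
            class = "pressure_screen")
}

#' @export
print.pressure_screen <- function(x, ...) {
  rng <- range(x$pressures)
  cat(sprintf("pressure screen: %d structures on %.3g-%.3g GPa (ref '%s')\n",
              ncol(x$enthalpy), rng[1], rng[2], x$reference))
  tab <- rle(x$most_stable)
  cat("most stable:", paste(sprintf("%s", tab$values), collapse = " -> "), "\n")
  if (nrow(x$crossovers)) {
    cat("crossovers vs reference:\n")
    for (i in seq_len(nrow(x$crossovers))) {
      cat(sprintf("  %s at %.4f GPa\n", x$crossovers$structure_id[i],
                  x$crossovers$pressure[i]))
    }
  } else {
    cat("no crossovers vs reference in range\n")
  }
  invisible(x)
}

#' Read pressure series from CSV
#'
#' Columns: `structure_id`, `pressure_gpa`, `e_kjmol_per_molecule`,
#' `v_a3_per_molecule`.
#'
#' @param path CSV path.
#' @return Named list of [pv_series()].
#' @export
read_pv_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("structure_id", "pressure_gpa", "e_kjmol_per_molecule",
            "v_a3_per_molecule")
  if (!all(need %in% names(df))) ps_format_error("bad pressure table header")
  ids <- unique(df$structure_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$structure_id == id, ]
    pv_series(id, sub$pressure_gpa, sub$e_kjmol_per_molecule,
              sub$v_a3_per_molecule)
  })
  names(out) <- ids
  out
}
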