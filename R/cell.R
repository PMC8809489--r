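# Unit cells and metric geometry. Cartesian frames follow the standard
# crystallographic convention: a along x, b in the xy plane.

# kJ/mol per GPa*A^3, i.e. Avogadro's number scaled to these units.
GPA_A3_TO_KJMOL <- 0.602214076

#' Construct a unit cell
#'
#' @param a,b,c cell lengths in Angstrom (> 0).
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`.
#' @examples
#' unit_cell(10, 10, 10)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  lens <- c(a = a, b = b, c = c)
  angs <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    ps_value_error("cell lengths must be finite and > 0")
  }
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180)) {
    ps_value_error("cell angles must lie in (0, 180) degrees")
  }
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  # metric volume must be a strictly positive real number
  arg <- .volume_arg(cell)
  if (!is.finite(arg) || arg <= 0) {
    ps_value_error("cell angles are metrically inconsistent (non-positive volume)")
  }
  cell
}

.volume_arg <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
}

#' Unit-cell volume
#'
#' Metric formula `V = abc sqrt(1 - cos^2 a - cos^2 b - cos^2 g + 2 cos a cos b cos g)`.
#'
#' @param cell a [unit_cell()].
#' @return Volume in cubic Angstrom.
#' @examples
#' cell_volume(unit_cell(10, 10, 10)) # 1000
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  cell$a * cell$b * cell$c * sqrt(.volume_arg(cell))
}

#' Lattice-vector matrix of a cell
#'
#' Columns are the Cartesian lattice vectors a, b, c (a along x, b in xy).
#'
#' @param cell a [unit_cell()].
#' @return A 3x3 numeric matrix; `cart = M %*% frac`.
#' @export
cell_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  av <- c(cell$a, 0, 0)
  bv <- c(cell$b * cg, cell$b * sg, 0)
  cx <- cell$c * cb
  cy <- cell$c * (ca - cb * cg) / sg
  cz <- sqrt(max(cell$c^2 - cx^2 - cy^2, 0))
  cbind(a = av, b = bv, c = c(cx, cy, cz))
}

#' Convert fractional to Cartesian coordinates
#'
#' @param frac numeric 3-vector or n x 3 matrix of fractional coordinates.
#' @param cell a [unit_cell()].
#' @return Cartesian coordinates in Angstrom, same shape as `frac`.
#' @export
frac_to_cart <- function(frac, cell) {
  m <- cell_matrix(cell)
  if (is.matrix(frac)) unname(t(m %*% t(frac))) else as.numeric(m %*% frac)
}

#' Convert Cartesian to fractional coordinates
#'
#' @param cart numeric 3-vector or n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param cell a [unit_cell()].
#' @return Fractional coordinates, same shape as `cart`.
#' @export
cart_to_frac <- function(cart, cell) {
  mi <- solve(cell_matrix(cell))
  if (is.matrix(cart)) unname(t(mi %*% t(cart))) else as.numeric(mi %*% cart)
}

#' Crystallographic density
#'
#' `rho = Z * M / (N_A * V)`, i.e. `Z * M / (0.602214076 * V)` with V in A^3.
#'
#' @param structure a [crystal_structure()]; `z_total` must be known (it is
#'   detected from the molecular connectivity when absent).
#' @param molar_mass molar mass of one molecule in g/mol; when `NULL` it is
#'   summed from the structure's atoms.
#' @return Density in g/cm^3.
#' @export
density <- function(structure, molar_mass = NULL) {
  stopifnot(inherits(structure, "crystal_structure"))
  v <- cell_volume(structure$cell)
  if (v <= 0) ps_value_error("zero cell volume")
  z <- structure$z_total
  if (is.null(z)) {
    z <- detect_zprime(structure)$z_total
  }
  if (is.null(molar_mass)) {
    cell_mass <- sum(atomic_mass(structure$sites$element)) * length(structure$ops)
    molar_mass <- cell_mass / z
  }
  z * molar_mass / (GPA_A3_TO_KJMOL * v)
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}
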