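# Covalent radii (Cordero et al. 2008, in Angstrom) and standard atomic
# masses (IUPAC 2021 abridged, g/mol) for the elements that occur in small
# organic crystals. Unknown symbols raise an element error.

.covalent_radii <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Br = 1.20,
  I = 1.39, Fe = 1.32, Zn = 1.22, Se = 1.20
)

.atomic_masses <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Br = 79.904, I = 126.90, Fe = 55.845, Zn = 65.38,
  Se = 78.971
)

check_elements <- function(elements) {
  bad <- setdiff(unique(elements), names(.covalent_radii))
  if (length(bad)) {
    ps_element_error(paste0(
      "unknown element symbol(s): ", paste(bad, collapse = ", ")
    ))
  }
  invisible(elements)
}

#' Covalent radius of an element
#'
#' @param element character vector of element symbols.
#' @return Covalent radii in Angstrom.
#' @export
covalent_radius <- function(element) {
  check_elements(element)
  unname(.covalent_radii[element])
}

#' Standard atomic mass of an element
#'
#' @param element character vector of element symbols.
#' @return Atomic masses in g/mol.
#' @export
atomic_mass <- function(element) {
  check_elements(element)
  unname(.atomic_masses[element])
}
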