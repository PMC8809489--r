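# Fixture builders shared across the suite. Everything is constructed in code
# at test time; no binary fixtures.

# P1 cube with a single carbon at the origin
single_atom_structure <- function(a = 10) {
  crystal_structure(
    "one_c", unit_cell(a, a, a), list(identity_symop()),
    data.frame(label = "C1", element = "C", fx = 0, fy = 0, fz = 0),
    z_total = 1L, z_prime = 1L)
}

# P1 cube with one C2 diatomic (bond 1.2 A along x)
diatomic_structure <- function(a = 10) {
  crystal_structure(
    "c2", unit_cell(a, a, a), list(identity_symop()),
    data.frame(label = c("C1", "C2"), element = "C",
               fx = c(0.30, 0.30 + 1.2 / a), fy = 0.5, fz = 0.5),
    z_total = 1L, z_prime = 1L)
}

# P1 cube holding two well-separated diatomics
two_diatomics_structure <- function(a = 12) {
  crystal_structure(
    "c2x2", unit_cell(a, a, a), list(identity_symop()),
    data.frame(label = c("C1", "C2", "C3", "C4"), element = "C",
               fx = c(0.20, 0.20 + 1.2 / a, 0.70, 0.70 + 1.2 / a),
               fy = c(0.25, 0.25, 0.75, 0.75), fz = 0.5),
    z_total = 2L, z_prime = 2L)
}

# toy-molecule crystal in P1 or P21 under a local seed
toy_crystal <- function(theta = 118, spacegroup = "P1", seed = 1, id = "toy") {
  withr::with_seed(seed, {
    generate_crystal(generate_toy_molecule(theta),
                     packing = list(spacegroup = spacegroup), id = id)
  })
}

# minimal CIF text for parser tests
minimal_cif_text <- function() {
  c("data_mini",
    "_cell_length_a 10.0",
    "_cell_length_b 10.0",
    "_cell_length_c 10.0",
    "_cell_angle_alpha 90.0",
    "_cell_angle_beta 90.0",
    "_cell_angle_gamma 90.0",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x,y,z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "C1 C 0.0 0.0 0.0")
}

# same crystal re-expressed: cyclic axis permutation (a,b,c) -> (b,c,a),
# a rigid rotation of the whole crystal in Cartesian space
permute_axes <- function(st) {
  cell <- st$cell
  newcell <- unit_cell(cell$b, cell$c, cell$a, cell$beta, cell$gamma, cell$alpha)
  sites <- st$sites
  sites[, c("fx", "fy", "fz")] <- sites[, c("fy", "fz", "fx")]
  crystal_structure(paste0(st$id, "_perm"), newcell, list(identity_symop()),
                    sites, z_total = st$z_total, z_prime = st$z_prime)
}
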