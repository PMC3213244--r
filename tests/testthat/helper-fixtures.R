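# shared fixtures, built in code at test time

path3_gnm_modes <- function() {
  pm <- point_model(cbind(0:2, 0, 0))
  solve_modes(assemble_gnm(contact_map_cutoff(pm, 1.5)))
}

two_node_gnm_modes <- function() {
  pm <- point_model(cbind(0:1, 0, 0))
  solve_modes(assemble_gnm(contact_map_cutoff(pm, 1.5)))
}

# connected ANM on a lattice rich enough to include diagonals
lattice_anm_modes <- function(n = 3, spacing = 1.8, cutoff = 2.6) {
  pm <- make_lattice(n, spacing)
  list(points = pm,
       modes = solve_modes(build_enm(pm, enm_definition("anm",
                                                        cutoff = cutoff))))
}

# brute-force O(N^2) cutoff contact oracle
brute_force_contacts <- function(xyz, cutoff) {
  n <- nrow(xyz)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff)
      out <- rbind(out, c(i, j))
  }
  out
}

# random orthonormal set of k columns in dimension d
random_orthonormal <- function(d, k, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(d * k), d, k)))
}

write_temp_pdb <- function(x, ...) {
  f <- tempfile(fileext = ".pdb")
  write_pdb(x, f, ...)
  f
}
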