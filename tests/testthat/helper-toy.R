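# shared toy structures; everything is generated in code

# single-site crystal: one He atom at a general position of a cubic cell
one_atom_crystal <- function(a = 5, frac = c(0.2, 0.3, 0.4)) {
  molecular_crystal(lattice_cell(a, a, a),
                    list(symmetry_op(diag(3))),
                    data.frame(element = "He", fa = frac[1], fb = frac[2],
                               fc = frac[3]))
}

# toy P2_1/c: 4 general positions from one single-atom "molecule"
p21c_crystal <- function() {
  ops <- lapply(c("x,y,z", "-x,y+1/2,-z+1/2", "-x,-y,-z", "x,-y+1/2,z+1/2"),
                parse_symop)
  molecular_crystal(lattice_cell(8, 9, 10, beta = 95), ops,
                    data.frame(element = "He", fa = 0.13, fb = 0.21, fc = 0.08))
}

# manual molecule construction for backend tests that bypass a crystal
manual_molecule <- function(element, xyz, site_id = seq_along(element)) {
  df <- data.frame(element = element, site_id = site_id,
                   op_id = 1L, oa = 0L, ob = 0L, oc = 0L,
                   fa = NA_real_, fb = NA_real_, fc = NA_real_,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  embedshield:::new_molecule(df, c(1L, 0L, 0L, 0L))
}

manual_cluster <- function(qm1, mm = NULL, qm2 = list()) {
  cluster_model(one_atom_crystal(), qm1, qm2, mm)
}

water_xyz <- function() {
  ang <- 104.5 * pi / 180
  matrix(c(0, 0.9572, 0.9572 * cos(ang),
           0, 0, 0.9572 * sin(ang),
           0, 0, 0), ncol = 3)
}

mm_frame <- function(q, pos, site_id = 99L) {
  pos <- matrix(pos, ncol = 3)
  data.frame(q = q, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             site_id = rep(site_id, length.out = length(q)))
}
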