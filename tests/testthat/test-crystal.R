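test_that("frac/cart transforms follow the crystallographic convention and round-trip", {
  cub <- lattice_cell(10, 10, 10)
  expect_equal(frac_to_cart(cub, c(0.5, 0.5, 0.5)), c(5, 5, 5))
  expect_equal(frac_to_cart(cub, c(0, 0, 0)), c(0, 0, 0))

  # metric-tensor oracle: G = t(M) M must equal the analytic metric
  mono <- lattice_cell(5, 6, 7, beta = 100)
  M <- cell_matrix(mono)
  d2r <- pi / 180
  G_ref <- matrix(c(25, 0, 5 * 7 * cos(100 * d2r),
                    0, 36, 0,
                    5 * 7 * cos(100 * d2r), 0, 49), 3)
  expect_equal(t(M) %*% M, G_ref, tolerance = 1e-12)
  expect_equal(sqrt(sum(frac_to_cart(mono, c(1, 0, 0))^2)), 5)

  set.seed(42)
  for (i in 1:20) {
    cell <- lattice_cell(runif(1, 3, 15), runif(1, 3, 15), runif(1, 3, 15),
                         runif(1, 60, 120), runif(1, 60, 120), runif(1, 60, 120))
    p <- runif(3, -2, 2)
    expect_equal(cart_to_frac(cell, frac_to_cart(cell, p)), p,
                 tolerance = 1e-10)
  }
})

test_that("degenerate cells are rejected", {
  expect_error(lattice_cell(5, 6, 7, 1, 1, 178), "volume|degenerate|angles")
  expect_error(lattice_cell(-1, 6, 7), "positive")
  expect_error(lattice_cell(5, 6, 7, gamma = 180), "angles")
})

test_that("symmetry xyz strings parse, format and apply correctly", {
  op <- parse_symop("-x, y+1/2, -z")
  expect_equal(op$rotation, diag(c(-1, 1, -1)))
  expect_equal(op$translation, c(0, 0.5, 0))
  expect_equal(format_symop(op), "-x,y+1/2,-z")
  op2 <- parse_symop("1/2+x, 1/2-y, z")
  expect_equal(op2$translation, c(0.5, 0.5, 0))
  expect_equal(op2$rotation[2, 2], -1)
  expect_error(symmetry_op(diag(c(2, 1, 1))), "determinant")
})

test_that("symmetry expansion wraps whole molecules into the cell", {
  # P1: the unit cell is the asymmetric unit
  cr1 <- make_toy_crystal("P1", seed = 1)
  mols <- expand_symmetry(cr1)
  expect_length(mols, 1)
  expect_equal(as.matrix(mols[[1]][, c("fa", "fb", "fc")]),
               as.matrix(cr1$atoms[, c("fa", "fb", "fc")]),
               ignore_attr = TRUE)

  # screw-axis image of a single atom: (-x, y+1/2, -z) on (0.1, 0.1, 0.1)
  cr <- molecular_crystal(lattice_cell(5, 5, 5),
                          list(symmetry_op(diag(3)),
                               parse_symop("-x,y+1/2,-z")),
                          data.frame(element = "He", fa = 0.1, fb = 0.1, fc = 0.1))
  mols <- expand_symmetry(cr)
  expect_length(mols, 2)
  expect_equal(unlist(mols[[2]][1, c("fa", "fb", "fc")]),
               c(fa = 0.9, fb = 0.6, fc = 0.9))
})

test_that("a toy P2_1/c crystal expands to four molecules at general positions", {
  cr <- p21c_crystal()
  mols <- expand_symmetry(cr)
  expect_length(mols, 4)
  # brute-force oracle: apply each op, wrap, count distinct positions
  f0 <- unlist(cr$atoms[1, c("fa", "fb", "fc")])
  ref <- unique(t(vapply(cr$ops, function(op) {
    (op$rotation %*% f0 + op$translation) %% 1
  }, numeric(3))))
  got <- t(vapply(mols, function(m) {
    unlist(m[1, c("fa", "fb", "fc")]) %% 1
  }, numeric(3)))
  expect_equal(nrow(ref), 4)
  expect_equal(got[order(got[, 1]), ], ref[order(ref[, 1]), ],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("special-position duplicates merge to a single image", {
  cr <- molecular_crystal(lattice_cell(6, 6, 6),
                          list(symmetry_op(diag(3)),
                               parse_symop("-x,-y,-z")),
                          data.frame(element = "He", fa = 0, fb = 0, fc = 0))
  expect_length(expand_symmetry(cr), 1)
})

test_that("supercell counts scale as n^3 and preserve site identity", {
  cr1 <- one_atom_crystal()
  expect_equal(nrow(build_supercell(cr1, 1)), 1)
  expect_equal(nrow(build_supercell(cr1, 9)), 729)
  expect_error(build_supercell(cr1, 4), "odd")

  cr <- make_toy_crystal("P21", seed = 1)      # 2 molecules x 3 atoms / cell
  atoms <- build_supercell(cr, 3)
  expect_equal(nrow(atoms), 162)
  mols <- build_supercell(cr, 3, molecules = TRUE)
  expect_length(mols, 54)
  # site multiset identical for every molecular copy
  sites <- vapply(mols, function(m) paste(sort(m$site_id), collapse = ","),
                  character(1))
  expect_equal(unique(sites), "1,2,3")
  expect_equal(as.vector(table(atoms$site_id)), rep(54, 3))
})

test_that("supercell enumeration matches the explicit oracle", {
  cr <- make_toy_crystal("P21", seed = 2)
  mols3 <- build_supercell(cr, 3, molecules = TRUE)
  cellmols <- expand_symmetry(cr)
  # oracle: every unit-cell molecule translated by each of the 27 offsets
  ref <- list()
  for (da in -1:1) for (db in -1:1) for (dc in -1:1) {
    for (m in cellmols) {
      xyz <- as.matrix(m[, c("x", "y", "z")]) +
        matrix(frac_to_cart(cr$cell, c(da, db, dc)), nrow(m), 3, byrow = TRUE)
      ref[[length(ref) + 1L]] <- xyz
    }
  }
  key <- function(x) paste(round(as.vector(x), 6), collapse = ",")
  expect_setequal(vapply(mols3, function(m) key(as.matrix(m[, c("x", "y", "z")])),
                         character(1)),
                  vapply(ref, key, character(1)))
})

test_that("molecule perception uses covalent radii, with and without periodicity", {
  # two He atoms far apart: no bond
  at <- data.frame(element = c("He", "He"), x = c(0, 10), y = 0, z = 0)
  expect_length(perceive_molecules(at), 2)

  # bent triatomic: one molecule of three atoms
  w <- water_xyz()
  at <- data.frame(element = c("O", "H", "H"), x = w[, 1], y = w[, 2], z = w[, 3])
  mols <- perceive_molecules(at)
  expect_length(mols, 1)
  expect_equal(nrow(mols[[1]]), 3)

  # diatomic split across the cell boundary: bonded only under minimum image
  cell <- lattice_cell(5, 5, 5)
  at <- data.frame(element = c("N", "N"), fa = c(0.9, 0.1), fb = 0.2, fc = 0.2)
  expect_length(perceive_molecules(at, cell, periodic = FALSE), 2)
  mols <- perceive_molecules(at, cell, periodic = TRUE)
  expect_length(mols, 1)
  # unwrapped: atoms end up 1.0 A apart in Cartesian space
  m <- mols[[1]]
  expect_equal(sqrt(sum((unlist(m[1, c("x", "y", "z")]) -
                         unlist(m[2, c("x", "y", "z")]))^2)), 1.0,
               tolerance = 1e-10)

  expect_error(perceive_molecules(data.frame(element = "Xx", x = 0, y = 0, z = 0)),
               "unknown element")
})

test_that("expansion then perception recovers ops x molecules for general positions", {
  cr <- p21c_crystal()
  atoms <- do.call(rbind, lapply(expand_symmetry(cr), as.data.frame))
  mols <- perceive_molecules(atoms, cr$cell, periodic = FALSE)
  expect_length(mols, length(cr$ops) * 1)
})

test_that("CIF files parse in both symmetry dialects", {
  cif <- c(
    "data_toy",
    "_cell_length_a 5.0",
    "_cell_length_b 5.5",
    "_cell_length_c 6.0",
    "_cell_angle_alpha 90",
    "_cell_angle_beta 100",
    "_cell_angle_gamma 90",
    "loop_",
    "_space_group_symop_operation_xyz",
    "'x, y, z'",
    "'-x, y+1/2, -z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "O1 O 0.2800 0.2200 0.3100",
    "H1 H 0.4100 0.2600 0.3900",
    "H2 H 0.1900 0.3300 0.4200")
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, f)
  cr <- read_cif(f)
  expect_equal(cr$cell$b, 5.5)
  expect_length(cr$ops, 2)
  expect_equal(cr$ops[[2]]$translation, c(0, 0.5, 0))
  expect_equal(cr$atoms$element, c("O", "H", "H"))
  expect_equal(cr$atoms$fa, c(0.28, 0.41, 0.19))

  # legacy dialect with numbered entries and site uncertainties
  cif2 <- sub("_space_group_symop_operation_xyz", "_symmetry_equiv_pos_as_xyz", cif)
  cif2 <- sub("^O1 O 0.2800", "O1 O 0.2800(3)", cif2)
  f2 <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif2, f2)
  cr2 <- read_cif(f2)
  expect_equal(cr2$atoms$fa[1], 0.28)
  expect_length(cr2$ops, 2)
})

test_that("XYZ export writes element and Cartesian columns with the molecule id", {
  cr <- make_toy_crystal("P1", seed = 1)
  m <- expand_symmetry(cr)[[1]]
  txt <- write_xyz(m)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(lines[1], "3")
  expect_match(lines[2], "mol_id")
  expect_match(lines[3], "^O ")
})
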