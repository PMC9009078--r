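test_that("QM2 shell selection matches brute-force distance enumeration", {
  # one atom per cubic cell: cutoff just above a catches the 6 face neighbors
  cr <- one_atom_crystal(a = 5)
  qm1 <- expand_symmetry(cr)[[1]]
  expect_length(select_qm2(cr, qm1, 0), 0)
  shell <- select_qm2(cr, qm1, 5.1)
  expect_length(shell, 6)
  d <- vapply(shell, function(m) attr(m, "dist"), numeric(1))
  expect_equal(d, rep(5, 6))
  expect_false(is.unsorted(d))

  # brute-force oracle over all 5^3 images for a lower-symmetry toy
  cr <- make_toy_crystal("P21", seed = 3)
  qm1 <- expand_symmetry(cr)[[1]]
  q1 <- as.matrix(qm1[, c("x", "y", "z")])
  mols <- build_supercell(cr, 5, molecules = TRUE)
  k1 <- embedshield:::mol_key(qm1)
  ref <- sort(Filter(function(x) x <= 3.4, vapply(mols, function(m) {
    if (embedshield:::mol_key(m) == k1) return(Inf)
    min(embedshield:::cross_dist(as.matrix(m[, c("x", "y", "z")]), q1))
  }, numeric(1))))
  shell <- select_qm2(cr, qm1, 3.4)
  expect_equal(vapply(shell, function(m) attr(m, "dist"), numeric(1)),
               ref, tolerance = 1e-12)
})

test_that("QM2 selection is monotone in the cutoff", {
  cr <- make_toy_crystal("P21", seed = 4)
  qm1 <- expand_symmetry(cr)[[1]]
  keys <- function(shell) vapply(shell, embedshield:::mol_key, character(1))
  prev <- character(0)
  for (cutoff in c(2.0, 2.8, 3.2, 3.6, 4.0)) {
    cur <- keys(select_qm2(cr, qm1, cutoff))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("an over-large cutoff is refused rather than silently truncated", {
  cr <- one_atom_crystal(a = 5)
  qm1 <- expand_symmetry(cr)[[1]]
  expect_error(select_qm2(cr, qm1, 11), "bounding")
})

test_that("MM field obeys the exact count identity N = n^3 N_cell - N_QM", {
  cr1 <- one_atom_crystal()
  qm1 <- expand_symmetry(cr1)[[1]]
  q <- charge_set(c(`1` = 0))
  mm <- build_mm_field(cr1, list(qm1), q, n = 9)
  expect_equal(nrow(mm), 728)

  cr <- make_toy_crystal("P21", seed = 1)
  mols <- expand_symmetry(cr)
  qcs <- charge_set(attr(cr, "ref_charges"))
  mm <- build_mm_field(cr, mols, qcs, n = 3)
  expect_equal(nrow(mm), 162 - 6)

  # identity across n and QM subset sizes (exhaustive toy oracle)
  for (n in c(1, 3, 5)) {
    for (nqm in 1:2) {
      mm <- build_mm_field(cr, mols[seq_len(nqm)], qcs, n = n)
      expect_equal(nrow(mm), n^3 * 6 - 3 * nqm)
    }
  }
})

test_that("MM charges map from sites and conserve neutrality", {
  cr <- make_toy_crystal("P21", seed = 1)
  mols <- expand_symmetry(cr)
  qcs <- charge_set(attr(cr, "ref_charges"))
  mm <- build_mm_field(cr, mols, qcs, n = 3)
  # neutral molecules, whole-molecule QM removal: field is exactly neutral
  expect_equal(sum(mm$q), 0, tolerance = 1e-12)
  expect_equal(unname(sort(unique(mm$q))), sort(unique(unname(qcs$q))))
  # per-site mapping
  expect_true(all(mm$q == unname(qcs$q[as.character(mm$site_id)])))

  expect_error(build_mm_field(cr, mols, c(`1` = -0.8, `2` = 0.4), n = 3),
               "missing site_id")
})

test_that("assembled clusters keep MM charges away from QM atoms", {
  cr <- make_toy_crystal("P21", seed = 2)
  qcs <- charge_set(attr(cr, "ref_charges"))
  cl <- build_cluster(cr, cutoff = 3.4, n_super = 3, charges = qcs)
  qm <- as.matrix(embedshield:::qm_atom_frame(cl)[, c("x", "y", "z")])
  mm <- as.matrix(cl$mm[, c("q", "x", "y", "z")])[, 2:4]
  expect_gt(min(embedshield:::cross_dist(mm, qm)), 1e-4)
  expect_gt(length(cl$qm2), 0)
})

test_that("freeze mask frees exactly the QM1 hydrogens", {
  cr <- make_toy_crystal("P21", seed = 1)
  cl <- build_cluster(cr, cutoff = 3.4, n_super = 3,
                      charges = charge_set(attr(cr, "ref_charges")))
  fm <- freeze_mask(cl)
  expect_equal(fm, cl$qm1$element == "H")
  expect_equal(sum(fm), 2)

  # no hydrogens: empty mask with a warning
  cr2 <- one_atom_crystal()
  cl2 <- cluster_model(cr2, expand_symmetry(cr2)[[1]], list())
  expect_warning(fm2 <- freeze_mask(cl2), "no hydrogen")
  expect_false(any(fm2))
})

test_that("rebuilding from unchanged coordinates is the identity", {
  cr <- make_toy_crystal("P21", seed = 5)
  cl <- build_cluster(cr, cutoff = 3.4, n_super = 3,
                      charges = charge_set(attr(cr, "ref_charges")))
  cl2 <- rebuild_cluster(cl, as.matrix(cl$qm1[, c("x", "y", "z")]))
  expect_equal(as.data.frame(cl2$qm1), as.data.frame(cl$qm1), tolerance = 1e-12)
  expect_equal(cl2$mm$x, cl$mm$x, tolerance = 1e-12)
})

test_that("hydrogen displacements propagate to every symmetry image", {
  # P1: pure translation symmetry, images shift by the same vector
  cr <- make_toy_crystal("P1", cell = lattice_cell(4.6, 5.0, 5.4, beta = 100),
                         seed = 1)
  cl <- build_cluster(cr, cutoff = 3.8, n_super = 3,
                      charges = charge_set(attr(cr, "ref_charges")))
  newc <- as.matrix(cl$qm1[, c("x", "y", "z")])
  hrow <- which(cl$qm1$element == "H")[1]
  hsite <- cl$qm1$site_id[hrow]
  newc[hrow, 1] <- newc[hrow, 1] + 0.1
  cl2 <- rebuild_cluster(cl, newc)
  moved <- cl2$mm$site_id == hsite
  expect_true(any(moved))
  expect_equal(cl2$mm$x[moved] - cl$mm$x[moved], rep(0.1, sum(moved)),
               tolerance = 1e-10)
  expect_equal(cl2$mm$y[moved], cl$mm$y[moved], tolerance = 1e-10)

  # P2_1: the image displacement is the symmetry-rotated displacement
  cr <- make_toy_crystal("P21", seed = 6)
  cl <- build_cluster(cr, cutoff = 3.4, n_super = 3,
                      charges = charge_set(attr(cr, "ref_charges")))
  newc <- as.matrix(cl$qm1[, c("x", "y", "z")])
  hrow <- which(cl$qm1$element == "H")[1]
  hsite <- cl$qm1$site_id[hrow]
  disp <- c(0.07, -0.04, 0.05)
  newc[hrow, ] <- newc[hrow, ] + disp
  cl2 <- rebuild_cluster(cl, newc)
  M <- cell_matrix(cr$cell)
  for (oi in seq_along(cr$ops)) {
    sel <- cl$mm$site_id == hsite & cl$mm$op_id == oi
    if (!any(sel)) next
    Rc <- M %*% cr$ops[[oi]]$rotation %*% solve(M)   # Cartesian image of the op
    dref <- as.numeric(Rc %*% disp)
    dx <- cbind(cl2$mm$x - cl$mm$x, cl2$mm$y - cl$mm$y, cl2$mm$z - cl$mm$z)[sel, , drop = FALSE]
    expect_equal(dx, matrix(dref, nrow(dx), 3, byrow = TRUE),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("rebuild refuses moved frozen atoms and incongruent input", {
  cr <- make_toy_crystal("P21", seed = 1)
  cl <- build_cluster(cr, cutoff = 3.4, n_super = 3,
                      charges = charge_set(attr(cr, "ref_charges")))
  newc <- as.matrix(cl$qm1[, c("x", "y", "z")])
  orow <- which(cl$qm1$element == "O")[1]
  newc[orow, 1] <- newc[orow, 1] + 1e-3
  expect_error(rebuild_cluster(cl, newc), "frozen atom")
  expect_error(rebuild_cluster(cl, newc[1:2, ]), "matrix")
})

test_that("rebuild is idempotent", {
  cr <- make_toy_crystal("P21", seed = 7)
  cl <- build_cluster(cr, cutoff = 3.4, n_super = 3,
                      charges = charge_set(attr(cr, "ref_charges")))
  newc <- as.matrix(cl$qm1[, c("x", "y", "z")])
  hrow <- which(cl$qm1$element == "H")
  newc[hrow, ] <- newc[hrow, ] + 0.05
  cl2 <- rebuild_cluster(cl, newc)
  cl3 <- rebuild_cluster(cl2, newc)
  expect_equal(as.data.frame(cl3$qm1), as.data.frame(cl2$qm1), tolerance = 1e-12)
  expect_equal(cl3$mm$z, cl2$mm$z, tolerance = 1e-12)
})
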