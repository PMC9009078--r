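#' Embedded cluster model
#'
#' The three-layer model used for molecular-crystal shielding calculations:
#' a central asymmetric-unit molecule (QM1) whose nuclei are reported, the
#' first shell of neighbouring molecules (QM2) treated at the same quantum
#' level, and the remaining crystal represented as a lattice of point
#' charges (MM).
#'
#' @param crystal the generating [molecular_crystal()].
#' @param qm1 central `molecule`.
#' @param qm2 list of shell molecules.
#' @param mm point-charge data.frame (`q`, `x`, `y`, `z`, `site_id`, ...),
#'   or `NULL` before charges are available.
#' @param charges the [charge_set()] the MM field was built from, if any.
#' @param cutoff QM2 selection cutoff (Angstrom).
#' @param n_super MM supercell multiplicity.
#' @return object of class `cluster_model`.
#' @export
cluster_model <- function(crystal, qm1, qm2, mm = NULL, charges = NULL,
                          cutoff = NA_real_, n_super = NA_integer_) {
  stopifnot(inherits(crystal, "molecular_crystal"))
  qk <- vapply(qm2, mol_key, character(1))
  if (mol_key(qm1) %in% qk) stop("qm1 must not appear in the qm2 shell")
  cl <- structure(list(crystal = crystal, qm1 = qm1, qm2 = qm2, mm = mm,
                       charges = charges, cutoff = cutoff, n_super = n_super),
                  class = "cluster_model")
  if (!is.null(mm)) check_mm_clearance(cl)
  cl
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> QM1: %d atoms | QM2: %d molecules (%d atoms) | MM: %s charges\n",
              nrow(x$qm1), length(x$qm2),
              sum(vapply(x$qm2, nrow, integer(1))),
              if (is.null(x$mm)) "no" else nrow(x$mm)))
  cat(sprintf("  cutoff %.2f A, supercell %s\n", x$cutoff, x$n_super))
  invisible(x)
}

qm_atom_frame <- function(cluster) {
  do.call(rbind, c(list(as.data.frame(cluster$qm1)),
                   lapply(cluster$qm2, as.data.frame)))
}

# invariant: no MM charge within 1e-4 A of any QM atom
check_mm_clearance <- function(cluster, tol = 1e-4) {
  if (is.null(cluster$mm) || !nrow(cluster$mm)) return(invisible(TRUE))
  qm <- as.matrix(qm_atom_frame(cluster)[, c("x", "y", "z")])
  mm <- as.matrix(cluster$mm[, c("x", "y", "z")])
  # chunk to bound memory on large supercells
  step <- 5000L
  for (i0 in seq(1L, nrow(mm), by = step)) {
    i1 <- min(i0 + step - 1L, nrow(mm))
    if (min(cross_dist(mm[i0:i1, , drop = FALSE], qm)) <= tol) {
      stop("MM point charge coincides with a QM atom position")
    }
  }
  invisible(TRUE)
}

#' Select the QM2 shell around a central molecule
#'
#' Returns every distinct molecular image (over all symmetry copies and
#' lattice translations within a bounding supercell) having at least one
#' atom within `cutoff` of any QM1 atom, sorted by that minimum distance.
#' All atoms, hydrogens included, enter the distance criterion.
#'
#' @param crystal a [molecular_crystal()].
#' @param qm1 the central `molecule` (an image from this crystal).
#' @param cutoff shell cutoff in Angstrom.
#' @param n_bound bounding supercell multiplicity used for the search.
#' @return list of `molecule` objects, nearest first, with the contact
#'   distance stored in attribute `"dist"`.
#' @export
select_qm2 <- function(crystal, qm1, cutoff, n_bound = 5) {
  if (!is.finite(cutoff) || cutoff < 0) stop("cutoff must be >= 0")
  k <- (n_bound - 1) / 2
  mols <- build_supercell(crystal, n_bound, molecules = TRUE)
  q1 <- as.matrix(qm1[, c("x", "y", "z")])
  q1key <- mol_key(qm1)
  wraps <- lapply(expand_symmetry(crystal), function(m) {
    c(m$oa[1], m$ob[1], m$oc[1])
  })
  opids <- vapply(expand_symmetry(crystal), function(m) m$op_id[1], integer(1))
  sel <- list(); d <- numeric()
  for (m in mols) {
    if (mol_key(m) == q1key) next
    dm <- min(cross_dist(as.matrix(m[, c("x", "y", "z")]), q1))
    if (dm <= cutoff) {
      id <- attr(m, "mol_id")
      w <- wraps[[match(id[1], opids)]]
      if (any(abs(id[2:4] - w) >= k)) {
        stop(sprintf(
          "QM2 shell reaches the boundary of the bounding %dx%dx%d supercell; increase n_bound",
          n_bound, n_bound, n_bound))
      }
      attr(m, "dist") <- dm
      sel[[length(sel) + 1L]] <- m
      d <- c(d, dm)
    }
  }
  sel[order(d)]
}

#' Build the MM point-charge field
#'
#' Places one point charge at every atom position of the `n` x `n` x `n`
#' supercell except positions occupied by QM1/QM2 atoms.  Charges are the
#' converged per-site values mapped onto every symmetry/translation image of
#' the generating asymmetric site.
#'
#' @param crystal a [molecular_crystal()].
#' @param qm_molecules list of molecules excluded from the field (QM1 and
#'   the QM2 shell).
#' @param charges a [charge_set()] or named numeric vector of per-site
#'   charges (names = `site_id`), covering every asymmetric site.
#' @param n odd supercell multiplicity (default 9).
#' @return data.frame of point charges: `q` (e), `x`, `y`, `z` (Angstrom)
#'   and the generating identifiers.
#' @export
build_mm_field <- function(crystal, qm_molecules, charges, n = 9) {
  q <- as_site_charges(charges)
  sites <- crystal$atoms$site_id
  if (!all(as.character(sites) %in% names(q))) {
    stop("charge set missing site_id(s): ",
         paste(setdiff(as.character(sites), names(q)), collapse = ", "))
  }
  atoms <- build_supercell(crystal, n)
  akey <- paste(atoms$site_id, atoms$op_id, atoms$oa, atoms$ob, atoms$oc)
  if (inherits(qm_molecules, "molecule")) qm_molecules <- list(qm_molecules)
  qmkey <- unlist(lapply(qm_molecules, function(m) {
    paste(m$site_id, m$op_id, m$oa, m$ob, m$oc)
  }))
  mm <- atoms[!(akey %in% qmkey), , drop = FALSE]
  mm$q <- unname(q[as.character(mm$site_id)])
  rownames(mm) <- NULL
  mm[, c("q", "x", "y", "z", "site_id", "op_id", "oa", "ob", "oc")]
}

#' Assemble the full QM1/QM2/MM cluster
#'
#' Convenience constructor running shell selection and, when charges are
#' supplied, MM-field construction.
#'
#' @inheritParams select_qm2
#' @inheritParams build_mm_field
#' @param charges optional [charge_set()]; without it the cluster carries no
#'   MM field (QM1/QM2 only).
#' @param n_super MM supercell multiplicity.
#' @param qm1_index which unit-cell molecule is the central one.
#' @return a [cluster_model()].
#' @export
build_cluster <- function(crystal, cutoff = 3.0, n_super = 9, charges = NULL,
                          n_bound = 5, qm1_index = 1) {
  mols <- expand_symmetry(crystal)
  qm1 <- mols[[qm1_index]]
  qm2 <- select_qm2(crystal, qm1, cutoff, n_bound = n_bound)
  mm <- NULL
  if (!is.null(charges)) {
    mm <- build_mm_field(crystal, c(list(qm1), qm2), charges, n = n_super)
  }
  cluster_model(crystal, qm1, qm2, mm, charges = charges,
                cutoff = cutoff, n_super = n_super)
}

#' Freeze mask for hydrogen-only relaxation
#'
#' Free atoms are exactly the QM1 hydrogens; every heavy atom and the whole
#' QM2/MM embedding stay frozen during the geometry relaxation handed to the
#' external engine.
#'
#' @param cluster a [cluster_model()].
#' @return logical vector over QM1 atoms, `TRUE` = free.
#' @export
freeze_mask <- function(cluster) {
  free <- cluster$qm1$element == "H"
  if (!any(free)) warning("QM1 contains no hydrogen atoms; empty freeze mask")
  free
}

#' Rebuild a cluster from updated QM1 coordinates
#'
#' After the external engine relaxes the QM1 hydrogens, the new positions
#' are propagated through each stored symmetry operation and lattice
#' translation to every QM2 molecule and MM site generated by the same
#' asymmetric site, and the whole cluster is reassembled.
#'
#' @param cluster a [cluster_model()] with an MM field or not.
#' @param new_qm1_coords numeric n x 3 matrix of Cartesian coordinates
#'   (Angstrom) congruent with the QM1 atom list; only freeze-mask-free
#'   atoms may differ from the current geometry.
#' @param tol_frozen maximum allowed displacement of a frozen atom.
#' @return the rebuilt [cluster_model()].
#' @export
rebuild_cluster <- function(cluster, new_qm1_coords, tol_frozen = 1e-6) {
  qm1 <- cluster$qm1
  new_qm1_coords <- as.matrix(new_qm1_coords)
  if (!all(dim(new_qm1_coords) == c(nrow(qm1), 3))) {
    stop("new_qm1_coords must be a ", nrow(qm1), " x 3 matrix")
  }
  old <- as.matrix(qm1[, c("x", "y", "z")])
  moved <- sqrt(rowSums((new_qm1_coords - old)^2))
  free <- cluster$qm1$element == "H"
  if (any(moved[!free] > tol_frozen)) {
    bad <- which(!free & moved > tol_frozen)[1]
    stop(sprintf("frozen atom %d (%s) moved by %.3g A",
                 bad, qm1$element[bad], moved[bad]))
  }
  crystal <- cluster$crystal
  # invert QM1's generating op to recover the new asymmetric-unit fractions
  op <- crystal$ops[[qm1$op_id[1]]]
  off <- c(qm1$oa[1], qm1$ob[1], qm1$oc[1])
  fr_new <- cart_to_frac(crystal$cell, new_qm1_coords)
  F0 <- t(solve(op$rotation) %*% (t(fr_new) - op$translation - off))
  asym <- crystal$atoms
  asym[qm1$site_id, c("fa", "fb", "fc")] <- F0
  crystal$atoms <- asym
  reresolve <- function(m) {
    key <- as.data.frame(m)[, c("site_id", "op_id", "oa", "ob", "oc")]
    new_molecule(resolve_atoms(crystal, key), attr(m, "mol_id"))
  }
  qm1_new <- reresolve(qm1)
  qm2_new <- lapply(cluster$qm2, reresolve)
  mm_new <- cluster$mm
  if (!is.null(mm_new)) {
    res <- resolve_atoms(crystal, mm_new[, c("site_id", "op_id", "oa", "ob", "oc")])
    mm_new$x <- res$x; mm_new$y <- res$y; mm_new$z <- res$z
  }
  cluster_model(crystal, qm1_new, qm2_new, mm_new, charges = cluster$charges,
                cutoff = cluster$cutoff, n_super = cluster$n_super)
}
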