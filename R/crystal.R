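# Bohr radius in Angstrom (CODATA 2018); used for atomic-unit Coulomb kernels.
.bohr_ang <- 0.529177210903

#' Covalent radii used for bond perception
#'
#' Single-bond covalent radii in Angstrom (Cordero et al. consensus values)
#' for the elements that occur in small-organic molecular crystals.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
covalent_radius <- function(element) {
  tab <- c(H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76,
           N = 0.71, O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41,
           Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06,
           K = 2.03, Ca = 1.76, Fe = 1.32, Zn = 1.22, Br = 1.20, I = 1.39)
  r <- tab[element]
  if (anyNA(r)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

# van der Waals radii (Bondi), Angstrom; ESP grid construction.
vdw_radius <- function(element) {
  tab <- c(H = 1.20, He = 1.40, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
           P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)
  r <- tab[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Lattice cell
#'
#' Triclinic cell parameters: lengths in Angstrom, angles in degrees.
#'
#' @param a,b,c cell lengths (Angstrom), > 0.
#' @param alpha,beta,gamma cell angles (degrees), in (0, 180).
#' @return an object of class `lattice_cell`.
#' @export
lattice_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c); ang <- c(alpha, beta, gamma)
  if (!all(is.finite(len)) || any(len <= 0)) stop("cell lengths must be positive")
  if (!all(is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "lattice_cell")
  if (cell_volume(cell) <= 0 || !is.finite(cell_volume(cell))) {
    stop("degenerate cell: volume <= 0")
  }
  cell
}

#' @export
print.lattice_cell <- function(x, ...) {
  cat(sprintf("<lattice_cell> a=%.4f b=%.4f c=%.4f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' Cell matrix (fractional -> Cartesian)
#'
#' Column matrix of the lattice vectors in the standard crystallographic
#' frame: a parallel to x, b in the xy-plane.  Cartesian = M %*% fractional.
#'
#' @param cell a [lattice_cell()].
#' @return 3x3 numeric matrix (Angstrom).
#' @export
cell_matrix <- function(cell) {
  d2r <- pi / 180
  ca <- cos(cell$alpha * d2r); cb <- cos(cell$beta * d2r)
  cg <- cos(cell$gamma * d2r); sg <- sin(cell$gamma * d2r)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("degenerate cell: volume <= 0")
  v <- sqrt(v2)
  matrix(c(cell$a, 0, 0,
           cell$b * cg, cell$b * sg, 0,
           cell$c * cb, cell$c * (ca - cb * cg) / sg, cell$c * v / sg),
         nrow = 3, ncol = 3)
}

#' @rdname cell_matrix
#' @export
cell_volume <- function(cell) {
  d2r <- pi / 180
  ca <- cos(cell$alpha * d2r); cb <- cos(cell$beta * d2r); cg <- cos(cell$gamma * d2r)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) return(0)
  cell$a * cell$b * cell$c * sqrt(v2)
}

#' Fractional/Cartesian coordinate transforms
#'
#' `frac_to_cart()` maps fractional coordinates to Cartesian Angstrom in the
#' standard frame (a along x, b in the xy-plane); `cart_to_frac()` is its
#' exact inverse.
#'
#' @param cell a [lattice_cell()].
#' @param frac,cart numeric 3-vector or n x 3 matrix.
#' @return same shape as the input.
#' @export
frac_to_cart <- function(cell, frac) {
  M <- cell_matrix(cell)
  if (is.matrix(frac)) t(M %*% t(frac)) else drop(M %*% frac)
}

#' @rdname frac_to_cart
#' @export
cart_to_frac <- function(cell, cart) {
  Mi <- solve(cell_matrix(cell))
  if (is.matrix(cart)) t(Mi %*% t(cart)) else drop(Mi %*% cart)
}

#' Symmetry operation on fractional coordinates
#'
#' @param rotation 3x3 integer-like matrix acting on fractional coordinates.
#' @param translation fractional 3-vector; reduced into `[0, 1)`.
#' @return object of class `symmetry_op`.
#' @export
symmetry_op <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  d <- det(rotation)
  if (abs(abs(d) - 1) > 1e-8) stop("rotation determinant must be +1 or -1")
  translation <- as.numeric(translation) %% 1
  structure(list(rotation = rotation, translation = translation),
            class = "symmetry_op")
}

#' @export
print.symmetry_op <- function(x, ...) {
  cat("<symmetry_op>", format_symop(x), "\n")
  invisible(x)
}

is_identity_op <- function(op, tol = 1e-8) {
  all(abs(op$rotation - diag(3)) < tol) && all(abs(op$translation) < tol)
}

#' Parse a symmetry operation xyz string
#'
#' Accepts the CIF `x,y,z` notation, e.g. `"-x, y+1/2, -z"` or
#' `"1/2+x, 1/2-y, z"`.
#'
#' @param s a single xyz string.
#' @return a [symmetry_op()].
#' @export
parse_symop <- function(s) {
  parts <- strsplit(gsub("[ '\"]", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry xyz string: ", s)
  rot <- matrix(0, 3, 3); tr <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize signed terms
    expr <- gsub("-", "+-", expr)
    toks <- strsplit(expr, "+", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    for (tk in toks) {
      sgn <- 1
      if (startsWith(tk, "-")) { sgn <- -1; tk <- substring(tk, 2) }
      if (grepl("[xyz]", tk)) {
        ax <- match(regmatches(tk, regexpr("[xyz]", tk)), c("x", "y", "z"))
        coefs <- gsub("[xyz]\\*?|\\*", "", tk)
        coef <- if (nzchar(coefs)) eval(parse(text = coefs)) else 1
        rot[i, ax] <- rot[i, ax] + sgn * coef
      } else {
        tr[i] <- tr[i] + sgn * eval(parse(text = tk))
      }
    }
  }
  symmetry_op(rot, tr)
}

#' @rdname parse_symop
#' @param op a [symmetry_op()].
#' @export
format_symop <- function(op) {
  axes <- c("x", "y", "z")
  comp <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      r <- op$rotation[i, j]
      if (abs(r) > 1e-10) {
        sgn <- if (r < 0) "-" else if (nzchar(s)) "+" else ""
        mag <- if (abs(abs(r) - 1) < 1e-10) "" else paste0(format(abs(r)), "*")
        s <- paste0(s, sgn, mag, axes[j])
      }
    }
    tr <- op$translation[i]
    if (abs(tr) > 1e-10) {
      fr <- .as_fraction(tr)
      s <- paste0(s, "+", fr)
    }
    comp[i] <- s
  }
  paste(comp, collapse = ",")
}

.as_fraction <- function(x, denoms = c(2, 3, 4, 6)) {
  for (d in denoms) {
    n <- round(x * d)
    if (abs(x - n / d) < 1e-9 && n != 0) return(paste0(n, "/", d))
  }
  format(x)
}

#' Molecular crystal
#'
#' A periodic molecular crystal: lattice cell, space-group operations, and
#' the asymmetric-unit atoms (fractional coordinates).  Every atom in any
#' expanded image is identified by its generating asymmetric site
#' (`site_id`), generating operation (`op_id`) and integer lattice
#' translation (`oa`, `ob`, `oc`).
#'
#' @param cell a [lattice_cell()].
#' @param ops list of [symmetry_op()]; must contain the identity.
#' @param atoms data.frame with columns `element`, `fa`, `fb`, `fc`
#'   (fractional coordinates of the asymmetric unit).
#' @return object of class `molecular_crystal`.
#' @export
molecular_crystal <- function(cell, ops, atoms) {
  stopifnot(inherits(cell, "lattice_cell"))
  if (inherits(ops, "symmetry_op")) ops <- list(ops)
  if (!length(ops) || !any(vapply(ops, is_identity_op, logical(1)))) {
    stop("ops must contain the identity operation")
  }
  need <- c("element", "fa", "fb", "fc")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)) || !nrow(atoms)) {
    stop("atoms must be a non-empty data.frame with element, fa, fb, fc")
  }
  atoms <- atoms[, need]
  atoms$site_id <- seq_len(nrow(atoms))
  structure(list(cell = cell, ops = ops, atoms = atoms),
            class = "molecular_crystal")
}

#' @export
print.molecular_crystal <- function(x, ...) {
  cat(sprintf("<molecular_crystal> %d asymmetric atoms, %d symmetry ops\n",
              nrow(x$atoms), length(x$ops)))
  print(x$cell)
  invisible(x)
}

# Resolve an image atom frame: fractional and Cartesian coordinates from
# (site_id, op_id, oa, ob, oc) against the crystal's asymmetric unit.
resolve_atoms <- function(crystal, key) {
  asym <- crystal$atoms
  F0 <- t(as.matrix(asym[key$site_id, c("fa", "fb", "fc")]))
  out <- key
  frac <- matrix(NA_real_, 3, nrow(key))
  for (oi in unique(key$op_id)) {
    sel <- key$op_id == oi
    op <- crystal$ops[[oi]]
    frac[, sel] <- op$rotation %*% F0[, sel, drop = FALSE] + op$translation
  }
  frac <- frac + rbind(key$oa, key$ob, key$oc)
  out$element <- asym$element[key$site_id]
  out$fa <- frac[1, ]; out$fb <- frac[2, ]; out$fc <- frac[3, ]
  cart <- cell_matrix(crystal$cell) %*% frac
  out$x <- cart[1, ]; out$y <- cart[2, ]; out$z <- cart[3, ]
  out
}

new_molecule <- function(df, mol_id) {
  attr(df, "mol_id") <- mol_id
  class(df) <- c("molecule", "data.frame")
  df
}

#' @export
print.molecule <- function(x, ...) {
  id <- attr(x, "mol_id")
  cat(sprintf("<molecule> %d atoms (%s)  mol_id: op %d, cell (%d,%d,%d)\n",
              nrow(x), paste(unique(x$element), collapse = ""),
              id[1], id[2], id[3], id[4]))
  invisible(x)
}

mol_key <- function(mol) {
  paste(attr(mol, "mol_id"), collapse = ",")
}

#' Expand space-group symmetry into unit-cell molecules
#'
#' Applies every symmetry operation to the asymmetric unit and wraps each
#' image so its centroid lies in `[0,1)^3` (whole molecules are translated;
#' atoms are never wrapped individually, so molecules stay intact).  Images
#' that coincide (special positions) are merged.
#'
#' @param crystal a [molecular_crystal()].
#' @param merge_tol coincidence tolerance (Angstrom) for merging duplicate
#'   images on special positions.
#' @param clash_tol minimum allowed interatomic distance (Angstrom) between
#'   distinct molecules; closer contacts signal an invalid structure.
#' @return list of `molecule` objects filling one unit cell.
#' @export
expand_symmetry <- function(crystal, merge_tol = 1e-3, clash_tol = 0.5) {
  asym <- crystal$atoms
  mols <- list()
  for (oi in seq_along(crystal$ops)) {
    op <- crystal$ops[[oi]]
    F <- op$rotation %*% t(as.matrix(asym[, c("fa", "fb", "fc")])) +
      op$translation
    wrap <- -floor(rowMeans(F))
    key <- data.frame(site_id = asym$site_id, op_id = oi,
                      oa = wrap[1], ob = wrap[2], oc = wrap[3])
    mols[[length(mols) + 1L]] <- new_molecule(resolve_atoms(crystal, key),
                                              c(oi, wrap))
  }
  # merge special-position duplicates: all atoms coincide pairwise
  keep <- rep(TRUE, length(mols))
  for (i in seq_along(mols)) {
    if (!keep[i]) next
    for (j in seq_along(mols)) {
      if (j <= i || !keep[j]) next
      ci <- as.matrix(mols[[i]][, c("x", "y", "z")])
      cj <- as.matrix(mols[[j]][, c("x", "y", "z")])
      if (nrow(ci) == nrow(cj) &&
          max(sqrt(rowSums((ci[order(ci[, 1], ci[, 2], ci[, 3]), , drop = FALSE] -
                            cj[order(cj[, 1], cj[, 2], cj[, 3]), , drop = FALSE])^2))) < merge_tol) {
        keep[j] <- FALSE
      }
    }
  }
  mols <- mols[keep]
  # clash check between distinct molecules
  if (length(mols) > 1) {
    for (i in seq_along(mols)) {
      for (j in seq_along(mols)) {
        if (j <= i) next
        d <- min(cross_dist(as.matrix(mols[[i]][, c("x", "y", "z")]),
                            as.matrix(mols[[j]][, c("x", "y", "z")])))
        if (d < clash_tol) {
          stop(sprintf("overlapping molecules: images %d and %d clash at %.3f A",
                       i, j, d))
        }
      }
    }
  }
  mols
}

# all pairwise distances between rows of two n x 3 matrices
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Build an n x n x n supercell centered on the origin cell
#'
#' @param crystal a [molecular_crystal()].
#' @param n odd supercell multiplicity; offsets range over
#'   `-(n-1)/2 ... +(n-1)/2` in each direction.
#' @param molecules if `TRUE` return a list of `molecule` objects, otherwise
#'   one atom data.frame.
#' @return atom data.frame (or list of molecules) covering the supercell;
#'   every atom keeps its generating `site_id`.
#' @export
build_supercell <- function(crystal, n = 9, molecules = FALSE) {
  if (n %% 2 == 0 || n < 1) stop("supercell multiplicity n must be odd >= 1")
  k <- (n - 1) / 2
  cellmols <- expand_symmetry(crystal)
  offs <- as.matrix(expand.grid(oa = -k:k, ob = -k:k, oc = -k:k))
  if (molecules) {
    out <- vector("list", nrow(offs) * length(cellmols))
    idx <- 1L
    for (r in seq_len(nrow(offs))) {
      for (m in cellmols) {
        key <- data.frame(site_id = m$site_id, op_id = m$op_id,
                          oa = m$oa + offs[r, 1], ob = m$ob + offs[r, 2],
                          oc = m$oc + offs[r, 3])
        id <- c(m$op_id[1], m$oa[1] + offs[r, 1], m$ob[1] + offs[r, 2],
                m$oc[1] + offs[r, 3])
        out[[idx]] <- new_molecule(resolve_atoms(crystal, key), id)
        idx <- idx + 1L
      }
    }
    return(out)
  }
  cellatoms <- do.call(rbind, lapply(cellmols, function(m) as.data.frame(m)))
  nc <- nrow(cellatoms); nr <- nrow(offs)
  key <- cellatoms[rep(seq_len(nc), times = nr),
                   c("site_id", "op_id", "oa", "ob", "oc")]
  key$oa <- key$oa + rep(offs[, 1], each = nc)
  key$ob <- key$ob + rep(offs[, 2], each = nc)
  key$oc <- key$oc + rep(offs[, 3], each = nc)
  rownames(key) <- NULL
  resolve_atoms(crystal, key)
}

#' Perceive molecules from an atom set
#'
#' Bonds atoms `i`, `j` whenever their distance does not exceed
#' `(r_cov(i) + r_cov(j)) * (1 + tol)` and returns the connected components.
#' With `periodic = TRUE` distances use the minimum-image convention and each
#' component is unwrapped across cell boundaries so it comes back intact.
#'
#' @param atoms data.frame with `element` and either Cartesian `x`,`y`,`z`
#'   or fractional `fa`,`fb`,`fc` columns (the latter require `cell`).
#' @param cell a [lattice_cell()]; required when `periodic = TRUE` or only
#'   fractional coordinates are present.
#' @param periodic logical; use minimum-image distances and unwrap.
#' @param tol fractional inflation of the covalent-radius sum (default 0.25).
#' @return list of `molecule` data.frames (Cartesian coordinates resolved).
#' @export
perceive_molecules <- function(atoms, cell = NULL, periodic = FALSE, tol = 0.25) {
  n <- nrow(atoms)
  r <- covalent_radius(atoms$element)
  rmax <- outer(r, r, "+") * (1 + tol)
  if (periodic) {
    if (is.null(cell)) stop("periodic perception requires a cell")
    if (!all(c("fa", "fb", "fc") %in% names(atoms))) {
      fr <- cart_to_frac(cell, as.matrix(atoms[, c("x", "y", "z")]))
      atoms$fa <- fr[, 1]; atoms$fb <- fr[, 2]; atoms$fc <- fr[, 3]
    }
    F <- as.matrix(atoms[, c("fa", "fb", "fc")])
    M <- cell_matrix(cell)
    # minimum-image pair shifts: for each pair the integer shift of j
    shift <- array(0, c(n, n, 3))
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
      dfr <- t(t(F) - F[i, ])          # frac j - i
      sh <- -round(dfr)
      dmin <- (dfr + sh) %*% t(M)
      D[i, ] <- sqrt(rowSums(dmin^2))
      shift[i, , ] <- sh
    }
  } else {
    if (!all(c("x", "y", "z") %in% names(atoms))) {
      if (is.null(cell)) stop("need Cartesian coordinates or a cell")
      cc <- frac_to_cart(cell, as.matrix(atoms[, c("fa", "fb", "fc")]))
      atoms$x <- cc[, 1]; atoms$y <- cc[, 2]; atoms$z <- cc[, 3]
    }
    D <- cross_dist(as.matrix(atoms[, c("x", "y", "z")]),
                    as.matrix(atoms[, c("x", "y", "z")]))
  }
  adj <- D <= rmax & upper.tri(D)
  adj <- adj | t(adj)
  comp <- rep(0L, n)
  ncomp <- 0L
  mols <- list()
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s; comp[s] <- ncomp
    place <- list()                    # per-atom accumulated frac shift
    place[[s]] <- c(0, 0, 0)
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(adj[i, ] & comp == 0L)
      for (j in nb) {
        comp[j] <- ncomp
        if (periodic) place[[j]] <- place[[i]] + shift[i, j, ]
        queue <- c(queue, j)
      }
    }
    idx <- which(comp == ncomp)
    sub <- atoms[idx, , drop = FALSE]
    if (periodic) {
      sh <- do.call(rbind, place[idx])
      F2 <- as.matrix(sub[, c("fa", "fb", "fc")]) + sh
      sub$fa <- F2[, 1]; sub$fb <- F2[, 2]; sub$fc <- F2[, 3]
      cc <- frac_to_cart(cell, F2)
      sub$x <- cc[, 1]; sub$y <- cc[, 2]; sub$z <- cc[, 3]
      if (all(c("oa", "ob", "oc") %in% names(sub))) {
        sub$oa <- sub$oa + sh[, 1]; sub$ob <- sub$ob + sh[, 2]
        sub$oc <- sub$oc + sh[, 3]
      }
    }
    rownames(sub) <- NULL
    id <- if (all(c("op_id", "oa") %in% names(sub))) {
      c(sub$op_id[1], sub$oa[1], sub$ob[1], sub$oc[1])
    } else c(NA_integer_, 0L, 0L, 0L)
    mols[[ncomp]] <- new_molecule(sub, id)
  }
  mols
}

#' Read a small-molecule CIF file
#'
#' Minimal reader for the fields the cluster pipeline needs: cell
#' parameters, symmetry operations (both the `_symmetry_equiv_pos_as_xyz`
#' and `_space_group_symop_operation_xyz` dialects) and the atom-site
#' fractional-coordinate loop.
#'
#' @param path path to a CIF file.
#' @return a [molecular_crystal()].
#' @export
read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  num <- function(tag) {
    ln <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (!length(ln)) stop("CIF missing ", tag)
    val <- sub("\\(.*\\)", "", strsplit(ln[1], "\\s+")[[1]][2])
    as.numeric(val)
  }
  cell <- lattice_cell(num("_cell_length_a"), num("_cell_length_b"),
                       num("_cell_length_c"), num("_cell_angle_alpha"),
                       num("_cell_angle_beta"), num("_cell_angle_gamma"))
  # locate loops
  loops <- which(lines == "loop_")
  ops <- NULL; atoms <- NULL
  for (L in loops) {
    i <- L + 1L
    hdr <- character()
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      hdr <- c(hdr, strsplit(lines[i], "\\s+")[[1]][1]); i <- i + 1L
    }
    body <- character()
    while (i <= length(lines) && nzchar(lines[i]) &&
           !startsWith(lines[i], "_") && lines[i] != "loop_" &&
           !startsWith(lines[i], "#")) {
      body <- c(body, lines[i]); i <- i + 1L
    }
    if (any(hdr %in% c("_symmetry_equiv_pos_as_xyz",
                       "_space_group_symop_operation_xyz"))) {
      col <- which(hdr %in% c("_symmetry_equiv_pos_as_xyz",
                              "_space_group_symop_operation_xyz"))
      xyz <- vapply(body, function(b) {
        if (grepl("'", b)) {
          regmatches(b, regexpr("'[^']*'", b)) |> (\(s) gsub("'", "", s))()
        } else {
          fields <- strsplit(b, "\\s+")[[1]]
          paste(fields[col:length(fields)][1:3], collapse = "")
        }
      }, character(1), USE.NAMES = FALSE)
      ops <- lapply(xyz, parse_symop)
    }
    if (any(hdr == "_atom_site_fract_x")) {
      fields <- strsplit(body, "\\s+")
      get <- function(tag) {
        j <- match(tag, hdr)
        if (is.na(j)) return(NULL)
        vapply(fields, `[[`, character(1), j)
      }
      el <- get("_atom_site_type_symbol")
      if (is.null(el)) el <- gsub("[0-9']+.*$", "", get("_atom_site_label"))
      strip <- function(v) as.numeric(sub("\\(.*\\)", "", v))
      atoms <- data.frame(element = el,
                          fa = strip(get("_atom_site_fract_x")),
                          fb = strip(get("_atom_site_fract_y")),
                          fc = strip(get("_atom_site_fract_z")))
    }
  }
  if (is.null(ops)) ops <- list(symmetry_op(diag(3)))
  if (is.null(atoms)) stop("CIF contains no atom_site loop")
  molecular_crystal(cell, ops, atoms)
}

#' Write molecules to XYZ format
#'
#' @param mols a `molecule` or list of molecules.
#' @param path optional output file; if `NULL` the text is returned.
#' @param comment optional comment line; defaults to the molecule id.
#' @return the XYZ text, invisibly when written to a file.
#' @export
write_xyz <- function(mols, path = NULL, comment = NULL) {
  if (inherits(mols, "molecule") || is.data.frame(mols)) mols <- list(mols)
  blocks <- vapply(mols, function(m) {
    id <- attr(m, "mol_id")
    cm <- if (!is.null(comment)) comment else {
      sprintf("mol_id op=%s cell=(%s,%s,%s)", id[1], id[2], id[3], id[4])
    }
    paste0(nrow(m), "\n", cm, "\n",
           paste(sprintf("%-2s %14.8f %14.8f %14.8f", m$element, m$x, m$y, m$z),
                 collapse = "\n"), "\n")
  }, character(1))
  txt <- paste(blocks, collapse = "")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path)
  invisible(txt)
}
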