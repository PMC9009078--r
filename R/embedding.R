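#' Per-site charge set
#'
#' Charges of the asymmetric-unit sites together with the self-consistency
#' iteration history.
#'
#' @param q named numeric vector of charges (e); names are `site_id`s.
#' @param iteration iteration index at which `q` was produced.
#' @param history list of earlier charge vectors (oldest first, including
#'   the current one as last element).
#' @param total_charge nominal molecular charge the set must sum to.
#' @return object of class `charge_set`.
#' @export
charge_set <- function(q, iteration = 0L, history = list(q),
                       total_charge = 0) {
  q <- unlist(q)
  if (is.null(names(q))) names(q) <- as.character(seq_along(q))
  if (abs(sum(q) - total_charge) > 1e-6) {
    stop(sprintf("charges sum to %.8f, expected molecular charge %g",
                 sum(q), total_charge))
  }
  structure(list(q = q, iteration = as.integer(iteration), history = history,
                 total_charge = total_charge),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat(sprintf("<charge_set> %d sites, iteration %d, total %.4f e\n",
              length(x$q), x$iteration, sum(x$q)))
  print(round(x$q, 4))
  invisible(x)
}

as_site_charges <- function(charges) {
  if (inherits(charges, "charge_set")) return(charges$q)
  q <- unlist(charges)
  if (is.null(names(q))) names(q) <- as.character(seq_along(q))
  q
}

#' Converge the embedding point charges self-consistently
#'
#' Iterates the atomic charges of the central molecule against the crystal
#' point-charge field they generate.  Iteration 0 evaluates the provider
#' with no surrounding charges; each later iteration rebuilds the MM field
#' of the full supercell (all atoms except QM1 itself) from the previous
#' charges, re-evaluates the provider in that field, and stops once the
#' chosen change metric falls to `tol`.
#'
#' @param provider a charge provider: `function(molecule, mm)` returning one
#'   charge per molecule atom, summing to the molecular charge.  `mm` is a
#'   point-charge data.frame (possibly empty).
#' @param crystal a [molecular_crystal()].
#' @param qm1 the central `molecule`; defaults to the first unit-cell
#'   molecule.
#' @param n supercell multiplicity for the field (default 9).
#' @param tol convergence threshold on the charge change (e); default 0.01.
#' @param max_iter iteration cap; exceeding it is an error carrying the
#'   history.
#' @param metric `"max"` (per-atom maximum absolute change, default) or
#'   `"rms"`.
#' @param total_charge molecular charge the provider must conserve.
#' @return a converged [charge_set()] with full history.
#' @export
converge_charges <- function(provider, crystal, qm1 = NULL, n = 9,
                             tol = 0.01, max_iter = 50,
                             metric = c("max", "rms"), total_charge = 0) {
  metric <- match.arg(metric)
  if (is.null(qm1)) qm1 <- expand_symmetry(crystal)[[1]]
  empty_mm <- data.frame(q = numeric(), x = numeric(), y = numeric(),
                         z = numeric(), site_id = integer())
  site <- as.character(qm1$site_id)
  delta <- function(qa, qb) {
    if (metric == "max") max(abs(qa - qb)) else sqrt(mean((qa - qb)^2))
  }
  q <- provider(qm1, empty_mm)
  if (abs(sum(q) - total_charge) > 1e-6) {
    stop("provider violated total-charge conservation at iteration 0")
  }
  names(q) <- site
  history <- list(q)
  for (k in seq_len(max_iter)) {
    mm <- build_mm_field(crystal, list(qm1), q, n = n)
    q_new <- provider(qm1, mm)
    if (abs(sum(q_new) - total_charge) > 1e-6) {
      stop("provider violated total-charge conservation at iteration ", k)
    }
    names(q_new) <- site
    history <- c(history, list(q_new))
    ch <- delta(q_new, q)
    q <- q_new
    if (ch <= tol) {
      return(charge_set(q, iteration = k, history = history,
                        total_charge = total_charge))
    }
  }
  cond <- structure(
    class = c("embedshield_nonconvergence", "error", "condition"),
    list(message = sprintf("charges not converged to %.3g in %d iterations",
                           tol, max_iter),
         call = sys.call(), history = history))
  stop(cond)
}

#' Fit point charges to an electrostatic potential grid
#'
#' Constrained least squares in the CHELPG spirit: minimizes
#' `sum_g (V_g - sum_i q_i / |r_g - r_i|)^2` subject to
#' `sum_i q_i = total_charge` (Lagrange multiplier).  The Coulomb kernel is
#' evaluated in atomic units; positions are supplied in Angstrom and
#' converted internally.
#'
#' @param positions n x 3 matrix of atom positions (Angstrom).
#' @param grid data.frame or matrix with columns `x`, `y`, `z` (Angstrom)
#'   and `v` (potential, hartree/e); at least as many points as atoms.
#' @param total_charge constrained total charge (e).
#' @return numeric vector of fitted charges (e).
#' @export
esp_fit_charges <- function(positions, grid, total_charge = 0) {
  positions <- as.matrix(positions)
  grid <- as.data.frame(grid)
  n <- nrow(positions)
  if (nrow(grid) < n) stop("need at least as many grid points as atoms")
  R <- cross_dist(as.matrix(grid[, c("x", "y", "z")]), positions) / .bohr_ang
  if (min(R) < 1e-8) stop("grid point coincides with an atom position")
  A <- 1 / R
  V <- grid$v
  # KKT system for the equality-constrained normal equations
  K <- rbind(cbind(2 * crossprod(A), rep(1, n)),
             c(rep(1, n), 0))
  rhs <- c(2 * crossprod(A, V), total_charge)
  sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
  if (is.null(sol) || rcond_est(K) < 1e-13) {
    warning("rank-deficient ESP system; returning minimum-norm solution")
    sv <- svd(K)
    pos <- sv$d > max(sv$d) * 1e-12
    sol <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% rhs) / sv$d[pos])
  }
  as.numeric(sol)[seq_len(n)]
}

rcond_est <- function(K) {
  tryCatch(1 / kappa(K, exact = FALSE), error = function(e) 0)
}

#' Coulomb potential of point charges
#'
#' Potential (hartree/e) at `points` generated by `charges` at `positions`;
#' all coordinates in Angstrom, converted to bohr for the kernel.
#'
#' @param points m x 3 matrix (Angstrom).
#' @param positions n x 3 matrix (Angstrom).
#' @param q numeric charges (e).
#' @return numeric vector of potentials, length m.
#' @export
coulomb_potential <- function(points, positions, q) {
  if (!length(q)) return(rep(0, nrow(as.matrix(points))))
  R <- cross_dist(as.matrix(points), as.matrix(positions)) / .bohr_ang
  as.numeric((1 / R) %*% q)
}

#' CHELPG-style ESP grid around a molecule
#'
#' Cubic lattice of spacing `spacing` clipped to the shell between
#' `rmin_scale` times the van der Waals radius of every atom and `rmax` of
#' any atom.  This is the dialect used by the package's analytic charge
#' backend; it is documented, deterministic, and not claimed identical to
#' any engine's grid.
#'
#' @param positions n x 3 matrix (Angstrom).
#' @param elements element symbols, length n.
#' @param spacing grid spacing (Angstrom, default 0.5).
#' @param rmin_scale exclusion-zone scale on the vdW radius (default 1.4).
#' @param rmax outer shell radius (Angstrom, default 2.8).
#' @return data.frame with columns `x`, `y`, `z`.
#' @export
esp_grid <- function(positions, elements, spacing = 0.5, rmin_scale = 1.4,
                     rmax = 2.8) {
  positions <- as.matrix(positions)
  rv <- vdw_radius(elements)
  lo <- apply(positions, 2, min) - rmax
  hi <- apply(positions, 2, max) + rmax
  ax <- lapply(1:3, function(i) seq(lo[i], hi[i], by = spacing))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  D <- cross_dist(pts, positions)
  inside <- sweep(D, 2, rmin_scale * rv, "<")
  keep <- !apply(inside, 1, any) & apply(D, 1, min) <= rmax
  as.data.frame(pts[keep, , drop = FALSE])
}

#' Analytic polarizable charge provider
#'
#' Deterministic stand-in for an engine's ESP-charge step.  Each atom
#' carries a reference charge; the external point-charge field polarizes
#' the molecule linearly: the mean-centred external potential at the atom
#' sites (atomic units) shifts each charge by `-chi * (V_i - mean(V))`,
#' conserving the total charge exactly.  The shifted charges then generate
#' a potential on a CHELPG-style grid from which the returned charges are
#' re-fitted with [esp_fit_charges()], so the full ESP machinery is
#' exercised on every call.
#'
#' @param ref_charges named numeric reference charges (e) by `site_id`.
#' @param chi linear response coefficient (e^2/hartree); small values give
#'   a contractive self-consistency loop.
#' @param fit if `FALSE`, skip the grid fit and return the shifted charges
#'   directly (faster; numerically equivalent for non-degenerate grids).
#' @return a provider `function(molecule, mm)` for [converge_charges()].
#' @export
mock_charge_provider <- function(ref_charges, chi = 0.2, fit = TRUE) {
  ref <- as_site_charges(ref_charges)
  force(chi); force(fit)
  function(mol, mm) {
    q0 <- unname(ref[as.character(mol$site_id)])
    pos <- as.matrix(mol[, c("x", "y", "z")])
    if (nrow(mm)) {
      V <- coulomb_potential(pos, as.matrix(mm[, c("x", "y", "z")]), mm$q)
      q <- q0 - chi * (V - mean(V))
    } else {
      q <- q0
    }
    if (!fit) return(q)
    grid <- esp_grid(pos, mol$element)
    grid$v <- coulomb_potential(as.matrix(grid), pos, q)
    esp_fit_charges(pos, grid, total_charge = sum(ref[as.character(mol$site_id)]))
  }
}

#' Linear-response test provider
#'
#' Provider implementing the exact affine map
#' `q_new = q0 + lambda * M %*% q_prev`, where `q_prev` is read back from
#' the per-site charges carried by the MM field (zero for an empty field).
#' With spectral radius of `lambda * M` below one, the self-consistency
#' loop contracts to the analytic fixed point `(I - lambda M)^-1 q0`.
#' `M` must have zero column sums so the total charge is conserved.
#'
#' @param q0 numeric base charges.
#' @param M square response matrix with zero column sums.
#' @param lambda scalar coupling.
#' @return a provider `function(molecule, mm)`.
#' @export
linear_response_provider <- function(q0, M, lambda = 1) {
  M <- as.matrix(M)
  if (max(abs(colSums(M))) > 1e-10) {
    stop("M must have zero column sums to conserve total charge")
  }
  force(q0); force(lambda)
  function(mol, mm) {
    site <- as.character(mol$site_id)
    if (nrow(mm)) {
      qprev <- vapply(site, function(s) mm$q[match(s, as.character(mm$site_id))],
                      numeric(1))
    } else {
      qprev <- rep(0, length(site))
    }
    as.numeric(q0 + lambda * (M %*% qprev))
  }
}
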