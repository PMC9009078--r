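#' Toy molecule template
#'
#' A three-atom bent polar molecule (water-like geometry) with neutral
#' reference charges; small enough for exhaustive oracles yet polar enough
#' that embedding fields shift the analytic shieldings measurably.
#'
#' @return list with `atoms` (data.frame `element`, `x`, `y`, `z` in a
#'   molecular frame) and `charges` (per-atom reference charges, e).
#' @export
toy_molecule <- function() {
  ang <- 104.5 * pi / 180
  list(atoms = data.frame(element = c("O", "H", "H"),
                          x = c(0, 0.9572, 0.9572 * cos(ang)),
                          y = c(0, 0, 0.9572 * sin(ang)),
                          z = c(0, 0, 0)),
       charges = c(-0.8, 0.4, 0.4))
}

#' Deterministic toy molecular crystal
#'
#' Small P1 or P2_1 crystal hosting one template molecule per asymmetric
#' unit at a general position, with known per-atom reference charges
#' (stored as attribute `ref_charges`).  The P2_1 variant has two
#' molecules per cell related by the 2_1 screw `(-x, y+1/2, -z)`.
#' A fixed seed perturbs the placement slightly so repeated builds with
#' different seeds give genuinely general positions; the same seed always
#' returns the identical crystal.
#'
#' @param spacegroup `"P1"` or `"P21"`.
#' @param cell a [lattice_cell()]; default a monoclinic 5 x 5.5 x 6
#'   Angstrom cell with beta = 100 degrees, packing the template so
#'   nearest intermolecular contacts fall in the 2.5-3.5 Angstrom range
#'   typical of hydrogen-bonded molecular crystals.
#' @param template molecule template as from [toy_molecule()].
#' @param seed placement seed.
#' @param center fractional position of the molecular centroid before the
#'   seeded perturbation.
#' @return a [molecular_crystal()] with attribute `ref_charges` (named by
#'   `site_id`).
#' @export
make_toy_crystal <- function(spacegroup = c("P1", "P21"), cell = NULL,
                             template = toy_molecule(), seed = 1,
                             center = c(0.28, 0.22, 0.31)) {
  spacegroup <- match.arg(spacegroup)
  if (is.null(cell)) cell <- lattice_cell(5, 5.5, 6, beta = 100)
  if (abs(sum(template$charges)) > 1e-9) stop("template molecule must be neutral")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cfrac <- center + stats::runif(3, -0.02, 0.02)
  xyz <- as.matrix(template$atoms[, c("x", "y", "z")])
  # seeded rigid rotation so the molecule sits at a general orientation
  th <- stats::runif(3, 0, 2 * pi)
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3)
  xyz <- xyz %*% t(Rz(th[1]) %*% Rx(th[2]) %*% Rz(th[3]))
  frac <- sweep(cart_to_frac(cell, xyz), 2,
                cfrac - colMeans(cart_to_frac(cell, xyz)), "+")
  atoms <- data.frame(element = template$atoms$element,
                      fa = frac[, 1], fb = frac[, 2], fc = frac[, 3])
  ops <- list(symmetry_op(diag(3)))
  if (spacegroup == "P21") {
    ops <- c(ops, list(symmetry_op(diag(c(-1, 1, -1)), c(0, 0.5, 0))))
  }
  crystal <- molecular_crystal(cell, ops, atoms)
  # validates placement, including clashes with periodic images
  q1 <- expand_symmetry(crystal)[[1]]
  mols <- build_supercell(crystal, 3, molecules = TRUE)
  k1 <- mol_key(q1)
  r1 <- covalent_radius(q1$element)
  for (m in mols) {
    if (mol_key(m) == k1) next
    D <- cross_dist(as.matrix(m[, c("x", "y", "z")]),
                    as.matrix(q1[, c("x", "y", "z")]))
    bond <- outer(covalent_radius(m$element), r1, "+") * 1.25
    if (any(D < bond)) {
      stop(sprintf("molecule clashes with its crystal images (%.2f A contact); cell too small",
                   min(D)))
    }
  }
  attr(crystal, "ref_charges") <- stats::setNames(template$charges,
                                                  crystal$atoms$site_id)
  crystal
}

#' Benchmark systems and their source structures
#'
#' The six amino-acid molecular crystals of the benchmark with their CSD
#' refcodes.  The structures are licensed and not bundled; the pipeline
#' accepts them as externally supplied CIF files.
#'
#' @return data.frame with `system`, `refcode`, `bundled`.
#' @export
csd_refcodes <- function() {
  data.frame(system = c("a-glycine", "l-threonine", "l-aspartic acid",
                        "l-cysteine", "l-serine", "l-alanine"),
             refcode = c("GLYCIN29", "LTHREO01", "LASPRT", "LCYSTN21",
                         "LSERIN01", "LALNIN12"),
             bundled = FALSE)
}

#' Load a benchmark crystal structure
#'
#' The benchmark structures are not distributable; this loader exists so
#' pipelines can be written uniformly, and fails with a pointer to the CSD
#' refcode unless the user supplies the CIF file.
#'
#' @param system benchmark system name (see [csd_refcodes()]).
#' @param cif_path optional path to a user-supplied CIF for that system.
#' @return a [molecular_crystal()] when `cif_path` is given.
#' @export
benchmark_crystal <- function(system, cif_path = NULL) {
  tab <- csd_refcodes()
  i <- match(system, tab$system)
  if (is.na(i)) stop("unknown benchmark system: ", system)
  if (is.null(cif_path)) {
    stop(sprintf(paste0("the %s structure (CSD refcode %s) is licensed and ",
                        "not bundled; supply it as cif_path"),
                 system, tab$refcode[i]))
  }
  read_cif(cif_path)
}

.fixture_md5 <- c(h1_shieldings.csv = "08d3cf136e861fa38cd76506cb3dbe4a",
                  c13_shieldings.csv = "9be23005756bc977f7a029a34e07bed7")

#' Packaged benchmark shielding and shift tables
#'
#' The published benchmark data for the six amino-acid crystals: 26
#' proton and 19 carbon nuclei, each with the experimental chemical shift
#' and the isotropic shieldings calculated with five electronic-structure
#' methods (PBE, TPSS, B3LYP, DSD-PBEP86, MP2 -- the latter two via the
#' DLPNO local-correlation scheme).  Values are transcribed to CSV at the
#' published precision; a checksum guards the transcription.
#'
#' @return list with `shieldings` (long [shielding_table()], 45 nuclei x 5
#'   methods), `shifts` (an [experimental_shifts()] table) and `methods`.
#' @export
load_benchmark_tables <- function() {
  files <- c("h1_shieldings.csv", "c13_shieldings.csv")
  paths <- vapply(files, function(f) {
    system.file("extdata", f, package = "embedshield", mustWork = TRUE)
  }, character(1))
  sums <- tools::md5sum(paths)
  bad <- unname(sums) != unname(.fixture_md5[files])
  if (any(bad)) stop("checksum mismatch on packaged table: ", files[bad][1])
  methods <- c("PBE", "TPSS", "B3LYP", "DSD-PBEP86", "MP2")
  wide <- do.call(rbind, lapply(paths, function(p) {
    utils::read.csv(p, check.names = FALSE)
  }))
  long <- do.call(rbind, lapply(methods, function(m) {
    data.frame(system = wide$system, nucleus = wide$nucleus,
               element = wide$element, method = m, sigma_ppm = wide[[m]])
  }))
  list(shieldings = shielding_table(long),
       shifts = experimental_shifts(wide[, c("system", "nucleus", "element",
                                             "delta_exp_ppm")]),
       methods = methods)
}

#' Run the full synthetic pipeline end to end
#'
#' Desk-scale demonstration: builds several seeded toy crystals, converges
#' the embedding charges with the analytic provider, evaluates the analytic
#' shielding backend for each cluster, manufactures "experimental" shifts
#' from a planted calibration line `delta = (sigma + noise - b0) / a0`,
#' and fits them back.  Recovery of the planted slope and intercept is the
#' pipeline's parameter-recovery check.
#'
#' @param n_crystals number of seeded toy crystals; the default mirrors the
#'   six crystal systems of the benchmark.
#' @param a0,b0 planted calibration slope and intercept.
#' @param noise_sd Gaussian noise on the manufactured shieldings (ppm);
#'   the default keeps the relative scatter at the few-percent-of-spread
#'   level the benchmark regressions exhibit.
#' @param cutoff QM2 shell cutoff (Angstrom).
#' @param n_super MM supercell multiplicity (desk scale default 5).
#' @param seed master seed.
#' @return list with the `shift_fit`, the shielding/shift tables, and the
#'   per-crystal converged charge sets.
#' @export
demo_pipeline <- function(n_crystals = 6, a0 = -1, b0 = 30, noise_sd = 0.01,
                          cutoff = 3.5, n_super = 5, seed = 1) {
  tabs <- list(); charges <- list()
  # graded cell volumes: each toy system is a genuinely different crystal
  # environment, as the benchmark spans six different structures
  scales <- seq(0.96, 1.12, length.out = max(n_crystals, 2))
  for (k in seq_len(n_crystals)) {
    s <- scales[k]
    cr <- make_toy_crystal("P21",
                           cell = lattice_cell(5 * s, 5.5 * s, 6 * s,
                                               beta = 100),
                           seed = seed + k)
    qm1 <- expand_symmetry(cr)[[1]]
    prov <- mock_charge_provider(attr(cr, "ref_charges"), fit = (k == 1))
    cs <- converge_charges(prov, cr, qm1, n = n_super)
    cl <- build_cluster(cr, cutoff = cutoff, n_super = n_super, charges = cs)
    tabs[[k]] <- mock_shieldings(cl, system = paste0("toy", k))
    charges[[k]] <- cs
  }
  sigma <- shielding_table(do.call(rbind, lapply(tabs, as.data.frame)))
  h <- sigma[sigma$element == "H", , drop = FALSE]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  shifts <- experimental_shifts(data.frame(
    system = h$system, nucleus = h$nucleus,
    delta_exp_ppm = (h$sigma_ppm + stats::rnorm(nrow(h), sd = noise_sd) - b0) / a0))
  fit <- fit_shieldings(shielding_table(h), shifts)
  list(fit = fit, shieldings = sigma, shifts = shifts, charges = charges,
       planted = c(slope = a0, intercept = b0), noise_sd = noise_sd)
}
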