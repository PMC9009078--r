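.known_methods <- c("PBE", "TPSS", "B3LYP", "DSD-PBEP86", "MP2")

#' Electronic-structure method specification
#'
#' Captures the settings encoded into an engine input deck: method, the
#' (larger) QM1 basis and (smaller) QM2 basis, dispersion and Coulomb /
#' exchange approximation tags, integration grid, and the pair-natural-
#' orbital accuracy tiers used by the multilevel local-correlation scheme
#' (pairs touching the QM1 fragment at the first tier, all remaining pairs
#' at the second).
#'
#' @param method one of `"PBE"`, `"TPSS"`, `"B3LYP"`, `"DSD-PBEP86"`,
#'   `"MP2"`.
#' @param qm1_basis basis for the central molecule (default `"pcSseg-3"`).
#' @param qm2_basis basis for the shell molecules (default `"def2-TZVP"`).
#' @param dispersion dispersion-correction tag; defaults to `"D3BJ"` for
#'   the DFT methods and none for MP2.
#' @param ri Coulomb/exchange approximation tag; defaults to `"RI"` for the
#'   (meta-)GGAs and `"RIJCOSX"` otherwise.
#' @param grid integration grid tag.
#' @param pno_levels length-2 character: PNO tier for QM1-coupled pairs and
#'   for the rest; used only by the correlated methods.
#' @return object of class `method_spec`.
#' @export
method_spec <- function(method, qm1_basis = "pcSseg-3",
                        qm2_basis = "def2-TZVP", dispersion = NULL,
                        ri = NULL, grid = "DefGrid3",
                        pno_levels = c("NormalPNO", "LoosePNO")) {
  method <- match.arg(method, .known_methods)
  if (!nzchar(qm1_basis) || !nzchar(qm2_basis)) stop("basis names must be non-empty")
  if (is.null(ri)) ri <- if (method %in% c("PBE", "TPSS")) "RI" else "RIJCOSX"
  if (is.null(dispersion)) dispersion <- if (method == "MP2") "" else "D3BJ"
  if (length(pno_levels) != 2) stop("pno_levels must have two entries")
  structure(list(method = method, qm1_basis = qm1_basis,
                 qm2_basis = qm2_basis, dispersion = dispersion, ri = ri,
                 grid = grid, pno_levels = pno_levels),
            class = "method_spec")
}

#' @export
print.method_spec <- function(x, ...) {
  cat(sprintf("<method_spec> %s  QM1: %s  QM2: %s  %s %s %s\n",
              x$method, x$qm1_basis, x$qm2_basis, x$ri, x$dispersion, x$grid))
  invisible(x)
}

is_correlated <- function(spec) spec$method %in% c("DSD-PBEP86", "MP2")

method_keyword <- function(spec) {
  switch(spec$method,
         "DSD-PBEP86" = "DLPNO-DSD-PBEP86",
         "MP2" = "DLPNO-MP2",
         spec$method)
}

#' Write an engine NMR input deck
#'
#' Emits an ORCA-style text deck for the embedded cluster: QM1 atoms first
#' (fragment 1, QM1 basis), then the QM2 shell (fragment 2, QM2 basis), an
#' external point-charge file reference, and an NMR property block
#' requesting shieldings for the fragment-1 nuclei only.  For the
#' correlated methods the multilevel PNO keywords are emitted.  The output
#' is a pure, byte-deterministic function of its inputs; the exact keyword
#' dialect is documented by the package's golden files.
#'
#' @param cluster a [cluster_model()].
#' @param spec a [method_spec()].
#' @param pc_file file name referenced for the external point charges.
#' @param charge,mult total charge and spin multiplicity of the QM system.
#' @param all_nuclei request shieldings for the whole QM region instead of
#'   QM1 only.
#' @return the deck as a single character string.
#' @export
write_nmr_input <- function(cluster, spec, pc_file = "cluster.pc",
                            charge = 0, mult = 1, all_nuclei = FALSE) {
  stopifnot(inherits(cluster, "cluster_model"), inherits(spec, "method_spec"))
  kw <- c(method_keyword(spec), spec$ri,
          if (nzchar(spec$dispersion)) spec$dispersion, spec$grid, "NMR")
  n1 <- nrow(cluster$qm1)
  qm2 <- do.call(rbind, lapply(cluster$qm2, as.data.frame))
  ntot <- n1 + if (is.null(qm2)) 0L else nrow(qm2)
  lines <- c(paste("!", paste(kw, collapse = " ")))
  if (!is.null(cluster$mm)) {
    lines <- c(lines, sprintf("%%pointcharges \"%s\"", pc_file))
  }
  if (is_correlated(spec)) {
    lines <- c(lines,
               "%mp2",
               "  UseMultilevel true",
               sprintf("  PNOFragment 1 %s", spec$pno_levels[1]),
               sprintf("  PNORest %s", spec$pno_levels[2]),
               "end")
  }
  last <- if (all_nuclei) ntot else n1
  lines <- c(lines,
             "%eprnmr",
             sprintf("  Nuclei = 1:%d { shift }", last),
             "end",
             sprintf("* xyz %d %d", charge, mult))
  atom_line <- function(el, x, y, z, frag, basis) {
    sprintf("%s(%d) %14.8f %14.8f %14.8f newGTO \"%s\" end",
            el, frag, x, y, z, basis)
  }
  lines <- c(lines,
             atom_line(cluster$qm1$element, cluster$qm1$x, cluster$qm1$y,
                       cluster$qm1$z, 1L, spec$qm1_basis))
  if (!is.null(qm2)) {
    lines <- c(lines,
               atom_line(qm2$element, qm2$x, qm2$y, qm2$z, 2L, spec$qm2_basis))
  }
  lines <- c(lines, "*")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write an external point-charge file
#'
#' Line 1 is the integer charge count; each following line is
#' `q x y z` (e, Angstrom) in fixed 6-decimal formatting.
#'
#' @param charges point-charge data.frame with columns `q`, `x`, `y`, `z`.
#' @param path optional output file.
#' @return the text, invisibly when written to a file.
#' @export
write_pointcharge_file <- function(charges, path = NULL) {
  n <- if (is.null(charges)) 0L else nrow(charges)
  body <- if (n) {
    paste0(sprintf("%.6f %.6f %.6f %.6f", charges$q, charges$x, charges$y,
                   charges$z), collapse = "\n")
  } else ""
  txt <- if (n) paste0(n, "\n", body, "\n") else "0\n"
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

#' Shielding table
#'
#' Long-format table of isotropic shieldings: one row per (system, nucleus,
#' method).
#'
#' @param df data.frame with columns `system`, `nucleus`, `element`,
#'   `method`, `sigma_ppm`.
#' @return validated data.frame of class `shielding_table`.
#' @export
shielding_table <- function(df) {
  need <- c("system", "nucleus", "element", "method", "sigma_ppm")
  if (!all(need %in% names(df))) {
    stop("shielding table needs columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[, need]
  if (!all(is.finite(df$sigma_ppm))) stop("non-finite shielding value")
  key <- paste(df$system, df$nucleus, df$element, df$method)
  if (anyDuplicated(key)) {
    stop("duplicate (system, nucleus, element, method): ",
         key[duplicated(key)][1])
  }
  class(df) <- c("shielding_table", "data.frame")
  df
}

#' Format and parse engine shielding output
#'
#' `format_shielding_output()` renders a shielding table in the text layout
#' the package's engine adapter understands; `parse_shieldings()` reads that
#' layout back into a [shielding_table()].  Round-trips exactly at six
#' decimals.
#'
#' @param table a [shielding_table()].
#' @param system,method identifiers stamped on parsed records.
#' @param text engine output text.
#' @return `parse_shieldings()`: a [shielding_table()].
#' @export
format_shielding_output <- function(table) {
  hdr <- c("CHEMICAL SHIELDINGS (ppm)",
           "-------------------------")
  body <- sprintf(" Nucleus %4d %-2s : sigma_iso = %14.6f",
                  seq_len(nrow(table)), table$element, table$sigma_ppm)
  lbl <- sprintf("   label %s", table$nucleus)
  paste0(paste(c(hdr, paste0(body, lbl)), collapse = "\n"), "\n")
}

#' @rdname format_shielding_output
#' @export
parse_shieldings <- function(text, system = "unknown", method = "unknown") {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  pat <- "^ Nucleus\\s+(\\d+)\\s+(\\S+)\\s*: sigma_iso =\\s+(-?[0-9.]+)(\\s+label\\s+(\\S+))?"
  hits <- regmatches(lines, regexec(pat, lines))
  hits <- hits[vapply(hits, length, integer(1)) > 0]
  if (!length(hits)) stop("no isotropic shielding block found in engine output")
  el <- vapply(hits, `[[`, character(1), 3)
  sig <- as.numeric(vapply(hits, `[[`, character(1), 4))
  lab <- vapply(hits, function(h) if (length(h) >= 6 && nzchar(h[[6]])) h[[6]] else NA_character_,
                character(1))
  if (anyNA(lab)) {
    idx <- stats::ave(seq_along(el), el, FUN = seq_along)
    lab[is.na(lab)] <- paste0(el[is.na(lab)], idx[is.na(lab)])
  }
  if (anyDuplicated(lab)) {
    stop("duplicated nucleus block in engine output: ", lab[duplicated(lab)][1])
  }
  if (anyNA(sig)) stop("malformed shielding value for nucleus ", lab[is.na(sig)][1])
  shielding_table(data.frame(system = system, nucleus = lab, element = el,
                             method = method, sigma_ppm = sig))
}

# default mock response constants: baseline shielding (ppm) and linear
# response to the site potential (ppm per hartree/e); tuned so that typical
# crystal fields shift sigma by ~1-5 ppm
.mock_sigma0 <- c(H = 30, C = 150, N = 220, O = 280, S = 550)
.mock_coef <- c(H = 20, C = 100, N = 120, O = 150, S = 300)

#' Deterministic analytic shielding backend
#'
#' Environment-sensitive closed-form stand-in for an engine's GIAO step:
#' each QM1 nucleus gets `sigma = sigma0(element) + c(element) * V`, where
#' `V` is the Coulomb potential (atomic units) at the nucleus generated by
#' the QM2 partial charges and the MM point charges.  Fully deterministic,
#' translation- and rotation-invariant.
#'
#' @param cluster a [cluster_model()].
#' @param charges per-site charges used for the QM2 atoms; defaults to the
#'   charge set stored in the cluster.  Required whenever a QM2 shell is
#'   present.
#' @param system,method identifiers stamped on the output records.
#' @return a [shielding_table()] with one row per QM1 nucleus (labels
#'   `element + index`).
#' @export
mock_shieldings <- function(cluster, charges = cluster$charges,
                            system = "toy", method = "MOCK") {
  qm1 <- cluster$qm1
  env_pos <- NULL; env_q <- numeric()
  if (length(cluster$qm2)) {
    if (is.null(charges)) stop("charges required to assign QM2 partial charges")
    q <- as_site_charges(charges)
    qm2 <- do.call(rbind, lapply(cluster$qm2, as.data.frame))
    env_pos <- as.matrix(qm2[, c("x", "y", "z")])
    env_q <- unname(q[as.character(qm2$site_id)])
  }
  if (!is.null(cluster$mm) && nrow(cluster$mm)) {
    env_pos <- rbind(env_pos, as.matrix(cluster$mm[, c("x", "y", "z")]))
    env_q <- c(env_q, cluster$mm$q)
  }
  pos <- as.matrix(qm1[, c("x", "y", "z")])
  V <- if (length(env_q)) coulomb_potential(pos, env_pos, env_q) else rep(0, nrow(pos))
  el <- qm1$element
  s0 <- .mock_sigma0[el]; cc <- .mock_coef[el]
  if (anyNA(s0)) stop("no mock response constants for element ",
                      el[is.na(s0)][1])
  idx <- stats::ave(seq_along(el), el, FUN = seq_along)
  shielding_table(data.frame(system = system, nucleus = paste0(el, idx),
                             element = el, method = method,
                             sigma_ppm = unname(s0 + cc * V)))
}

#' Export a shielding table as CSV
#'
#' @param table a [shielding_table()].
#' @param path output file.
#' @export
write_shielding_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shielding_csv
#' @export
read_shielding_csv <- function(path) {
  shielding_table(utils::read.csv(path))
}
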