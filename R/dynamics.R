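#' Snapshot schedule for the hydrogen-only MD protocol
#'
#' Defaults are the production protocol: 1 fs time step, 40 ps total run,
#' 1 ps equilibration, then 100 snapshots evenly separated by 0.3 ps
#' (first frame at 1.3 ps, last at 31.0 ps).
#'
#' @param dt_fs MD time step (fs).
#' @param total_ps total run length (ps).
#' @param equil_ps equilibration period (ps).
#' @param count number of snapshots.
#' @param interval_ps spacing between snapshots (ps).
#' @return object of class `snapshot_schedule`.
#' @export
snapshot_schedule <- function(dt_fs = 1, total_ps = 40, equil_ps = 1,
                              count = 100, interval_ps = 0.3) {
  vals <- c(dt_fs, total_ps, equil_ps, count, interval_ps)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all schedule parameters must be positive")
  }
  if (equil_ps + count * interval_ps > total_ps + 1e-9) {
    stop("schedule overruns the total run length")
  }
  structure(list(dt_fs = dt_fs, total_ps = total_ps, equil_ps = equil_ps,
                 count = as.integer(count), interval_ps = interval_ps),
            class = "snapshot_schedule")
}

#' @export
print.snapshot_schedule <- function(x, ...) {
  t <- snapshot_times(x)
  cat(sprintf("<snapshot_schedule> dt %g fs, %g ps total, %g ps equilibration, %d frames every %g ps (%.1f ... %.1f ps)\n",
              x$dt_fs, x$total_ps, x$equil_ps, x$count, x$interval_ps,
              t[1], t[length(t)]))
  invisible(x)
}

#' Snapshot times
#'
#' Frame times `t_k = equil + k * interval`, `k = 1 ... count`; every time
#' must fall on the MD step grid and inside the run.
#'
#' @param s a [snapshot_schedule()].
#' @return numeric vector of times (ps), strictly increasing.
#' @export
snapshot_times <- function(s) {
  t <- s$equil_ps + seq_len(s$count) * s$interval_ps
  if (t[length(t)] > s$total_ps + 1e-9) stop("schedule overruns the total run length")
  steps <- t * 1000 / s$dt_fs
  if (max(abs(steps - round(steps))) > 1e-6) {
    stop("snapshot times must be multiples of the MD time step")
  }
  t
}

#' Synthetic hydrogen-jitter trajectory
#'
#' Stand-in for an external MD engine under the production constraint that
#' only QM1 hydrogens move: each snapshot displaces every free hydrogen by
#' an independent isotropic Gaussian offset while heavy atoms stay at their
#' lattice positions.  Reproducible under `seed`.
#'
#' @param cluster a [cluster_model()].
#' @param amplitude per-coordinate displacement standard deviation
#'   (Angstrom).
#' @param count number of snapshots.
#' @param seed RNG seed.
#' @return list of `count` Cartesian n x 3 matrices for the QM1 atoms.
#' @export
jitter_trajectory <- function(cluster, amplitude, count = 100, seed = 1) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  base <- as.matrix(cluster$qm1[, c("x", "y", "z")])
  free <- cluster$qm1$element == "H"
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(count), function(k) {
    fr <- base
    if (any(free) && amplitude > 0) {
      fr[free, ] <- fr[free, ] +
        matrix(stats::rnorm(3 * sum(free), sd = amplitude), ncol = 3)
    }
    fr
  })
}

#' Average shielding tables over snapshots
#'
#' Arithmetic per-nucleus mean over a list of shielding tables with
#' identical nucleus sets (e.g. the single-point results of the MD
#' snapshots).
#'
#' @param tables list of [shielding_table()]s.
#' @param method method label stamped on the averaged table; defaults to
#'   the input label.
#' @return a [shielding_table()] with attribute `n_snapshots`.
#' @export
average_shieldings <- function(tables, method = NULL) {
  if (!length(tables)) stop("no tables to average")
  ref <- as.data.frame(tables[[1]])
  key <- function(t) nucleus_key(t)
  k0 <- key(ref)
  sig <- matrix(NA_real_, nrow(ref), length(tables))
  for (i in seq_along(tables)) {
    t <- as.data.frame(tables[[i]])
    m <- match(k0, key(t))
    if (anyNA(m) || nrow(t) != nrow(ref)) {
      stop("snapshot tables have mismatched nucleus sets")
    }
    sig[, i] <- t$sigma_ppm[m]
  }
  out <- ref
  out$sigma_ppm <- rowMeans(sig)
  if (!is.null(method)) out$method <- method
  out <- shielding_table(out)
  attr(out, "n_snapshots") <- length(tables)
  out
}

#' Vibrational (DIFF) correction
#'
#' Per-nucleus difference between the snapshot-averaged and the rigid
#' (static) shieldings, `delta_sigma = md_mean - static`.  Adding the
#' correction to the static table with [apply_correction()] reproduces the
#' MD mean exactly; computed at one cheap level of theory, it is applied
#' additively to results from any other level.
#'
#' @param static rigid-structure [shielding_table()].
#' @param md_mean snapshot-averaged [shielding_table()] over the same
#'   nuclei.
#' @return data.frame with columns `system`, `nucleus`, `element`,
#'   `dsigma_ppm`.
#' @export
diff_correction <- function(static, md_mean) {
  s <- as.data.frame(static); m <- as.data.frame(md_mean)
  idx <- match(nucleus_key(s, m), nucleus_key(m, s))
  if (anyNA(idx) || nrow(s) != nrow(m)) {
    stop("static and MD tables have mismatched nucleus sets")
  }
  data.frame(system = s$system, nucleus = s$nucleus, element = s$element,
             dsigma_ppm = m$sigma_ppm[idx] - s$sigma_ppm)
}

#' Multi-frame XYZ trajectory input/output
#'
#' `write_xyz_trajectory()` writes a list of coordinate frames for a fixed
#' atom template; `read_xyz_trajectory()` reads any multi-frame XYZ file.
#'
#' @param frames list of n x 3 Cartesian matrices.
#' @param template data.frame with an `element` column ordering the atoms.
#' @param path file path.
#' @return `read_xyz_trajectory()`: list of data.frames with `element`,
#'   `x`, `y`, `z`.
#' @export
write_xyz_trajectory <- function(frames, template, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    writeLines(c(as.character(nrow(fr)), sprintf("frame %d", i)), con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", template$element,
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz_trajectory
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    n <- as.integer(trimws(lines[i]))
    block <- lines[(i + 2L):(i + 1L + n)]
    f <- strsplit(trimws(block), "\\s+")
    frames[[length(frames) + 1L]] <- data.frame(
      element = vapply(f, `[[`, character(1), 1),
      x = as.numeric(vapply(f, `[[`, character(1), 2)),
      y = as.numeric(vapply(f, `[[`, character(1), 3)),
      z = as.numeric(vapply(f, `[[`, character(1), 4)))
    i <- i + 2L + n
  }
  frames
}
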