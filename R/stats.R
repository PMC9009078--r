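#' Experimental chemical shifts
#'
#' @param df data.frame with columns `system`, `nucleus`, `delta_exp_ppm`
#'   (and optionally `element`); (system, nucleus) must be unique.
#' @return validated data.frame of class `experimental_shifts`.
#' @export
experimental_shifts <- function(df) {
  need <- c("system", "nucleus", "delta_exp_ppm")
  if (!all(need %in% names(df))) {
    stop("shift table needs columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)
  key <- nucleus_key(df)
  if (anyDuplicated(key)) {
    stop("duplicate (system, nucleus): ", key[duplicated(key)][1])
  }
  if (!all(is.finite(df$delta_exp_ppm))) stop("non-finite shift value")
  class(df) <- c("experimental_shifts", "data.frame")
  df
}

# nucleus identity includes the element when both sides carry it: the
# benchmark tables reuse labels (e.g. COOH) across the 1H and 13C sets
nucleus_key <- function(df, other = NULL) {
  use_el <- "element" %in% names(df) &&
    (is.null(other) || "element" %in% names(other))
  if (use_el) paste(df$system, df$nucleus, df$element)
  else paste(df$system, df$nucleus)
}

.short_system <- function(system) {
  map <- c("l-alanine" = "ala", "a-glycine" = "gly", "l-serine" = "ser",
           "l-aspartic acid" = "asp", "l-cysteine" = "cys",
           "l-threonine" = "thr")
  out <- unname(map[system])
  out[is.na(out)] <- system[is.na(out)]
  out
}

#' Error metrics for predicted shifts
#'
#' Errors are `e = delta_calc - delta_exp`.  MAE is the mean absolute
#' error, MaxAE the maximum absolute error (with the label of the nucleus
#' attaining it), SDE the sample standard deviation of the errors (n - 1
#' denominator), and MSE the mean signed error.
#'
#' @param delta_calc,delta_exp numeric vectors (ppm), equal length.
#' @param labels optional nucleus labels for the MaxAE report.
#' @return list with `mae`, `maxae`, `maxae_label`, `sde`, `mse`.
#' @export
error_metrics <- function(delta_calc, delta_exp, labels = NULL) {
  if (!length(delta_calc) || length(delta_calc) != length(delta_exp)) {
    stop("delta_calc and delta_exp must be non-empty and of equal length")
  }
  e <- delta_calc - delta_exp
  i <- which.max(abs(e))
  list(mae = mean(abs(e)), maxae = abs(e)[i],
       maxae_label = if (!is.null(labels)) labels[i] else NA_character_,
       sde = if (length(e) > 1) stats::sd(e) else 0, mse = mean(e))
}

#' Predicted shifts from a shielding/shift calibration
#'
#' Inverts the referencing line `sigma = a * delta + b`:
#' `delta_calc = (sigma - b) / a`.
#'
#' @param sigma numeric shieldings (ppm).
#' @param a slope (unitless, non-zero).
#' @param b intercept (ppm).
#' @return numeric predicted shifts (ppm).
#' @export
predict_shifts <- function(sigma, a, b) {
  if (!is.finite(a) || a == 0) stop("slope a must be non-zero")
  (sigma - b) / a
}

#' Fit calculated shieldings against experimental shifts
#'
#' The linear referencing model of the benchmark: ordinary least squares of
#' the calculated shielding on the experimental shift
#' (`sigma = a * delta + b`, shielding as response), with the coefficient
#' of determination from that fit.  Predicted shifts are obtained by
#' inverting the fitted line, and the error statistics (MAE, MaxAE, SDE,
#' MSE) are computed on the same matched pairs.
#'
#' @param sigma a [shielding_table()] (one method, one element class, or
#'   filtered via `method`/`element`).
#' @param exp an [experimental_shifts()] table; matching is by
#'   (system, nucleus).
#' @param method optional method filter applied to `sigma`.
#' @param element optional element filter applied to `sigma`.
#' @return object of class `shift_fit`: coefficients, `r2`, error metrics,
#'   `n`, and the matched data.
#' @export
fit_shieldings <- function(sigma, exp, method = NULL, element = NULL) {
  s <- as.data.frame(sigma)
  if (!is.null(method)) s <- s[s$method == method, , drop = FALSE]
  if (!is.null(element)) s <- s[s$element == element, , drop = FALSE]
  if (length(unique(s$method)) > 1) {
    stop("sigma spans several methods; pass method = to select one")
  }
  e <- as.data.frame(exp)
  idx <- match(nucleus_key(s, e), nucleus_key(e, s))
  if (anyNA(idx)) {
    stop("no experimental shift for: ",
         paste(paste0(s$nucleus[is.na(idx)], "(", s$system[is.na(idx)], ")"),
               collapse = ", "))
  }
  d <- data.frame(system = s$system, nucleus = s$nucleus,
                  label = paste0(s$nucleus, "(", .short_system(s$system), ")"),
                  sigma = s$sigma_ppm, delta_exp = e$delta_exp_ppm[idx])
  if (nrow(d) < 3) stop("need at least 3 matched (sigma, delta) pairs")
  fit <- stats::lm(sigma ~ delta_exp, data = d)
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((d$sigma - mean(d$sigma))^2)
  d$delta_calc <- predict_shifts(d$sigma, a, b)
  d$error <- d$delta_calc - d$delta_exp
  m <- error_metrics(d$delta_calc, d$delta_exp, d$label)
  structure(list(coefficients = c(slope = a, intercept = b),
                 r2 = r2,
                 mae = m$mae, maxae = m$maxae, maxae_label = m$maxae_label,
                 sde = m$sde, mse = m$mse, n = nrow(d),
                 method = if (is.null(method)) unique(s$method) else method,
                 element = if (is.null(element)) paste(unique(s$element), collapse = "/") else element,
                 data = d, lm = fit),
            class = "shift_fit")
}

#' @export
print.shift_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Shielding/shift linear referencing fit (%s, %s, n = %d)\n",
              x$method, x$element, x$n))
  cat(sprintf("  sigma = a * delta_exp + b:  a = %.*f, b = %.*f ppm, R^2 = %.4f\n",
              digits, x$coefficients["slope"], digits,
              x$coefficients["intercept"], x$r2))
  cat(sprintf("  MAE %.*f | MaxAE %.*f (%s) | SDE %.*f | MSE %.2g ppm\n",
              digits, x$mae, digits, x$maxae, x$maxae_label, digits, x$sde,
              x$mse))
  invisible(x)
}

#' @export
summary.shift_fit <- function(object, ...) {
  print(object)
  cat("\nPer-nucleus errors (delta_calc - delta_exp, ppm):\n")
  d <- object$data
  print(data.frame(nucleus = d$label, delta_exp = d$delta_exp,
                   delta_calc = round(d$delta_calc, 2),
                   error = round(d$error, 2)), row.names = FALSE)
  invisible(object)
}

#' @export
coef.shift_fit <- function(object, ...) object$coefficients

#' @export
residuals.shift_fit <- function(object, ...) {
  stats::setNames(object$data$error, object$data$label)
}

#' Predict shifts from a fitted referencing model
#'
#' @param object a `shift_fit`.
#' @param newdata numeric shieldings (ppm) or a [shielding_table()]; the
#'   fit's own shieldings when omitted.
#' @param ... unused.
#' @return numeric predicted shifts (ppm).
#' @export
predict.shift_fit <- function(object, newdata = NULL, ...) {
  sigma <- if (is.null(newdata)) object$data$sigma
           else if (is.numeric(newdata)) newdata
           else as.data.frame(newdata)$sigma_ppm
  predict_shifts(sigma, object$coefficients["slope"],
                 object$coefficients["intercept"])
}

#' @export
plot.shift_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$delta_exp, d$sigma,
                 xlab = expression(delta[exp] ~ "(ppm)"),
                 ylab = expression(sigma[calc] ~ "(ppm)"),
                 main = sprintf("%s (%s): sigma = %.2f delta + %.2f",
                                x$method, x$element,
                                x$coefficients["slope"],
                                x$coefficients["intercept"]), ...)
  graphics::abline(x$coefficients["intercept"], x$coefficients["slope"])
  invisible(x)
}

#' Simulate shieldings from a fitted referencing model
#'
#' Draws shieldings at the observed experimental shifts from the fitted
#' line plus Gaussian noise with the residual standard deviation.
#'
#' @param object a `shift_fit`.
#' @param nsim number of simulated replicates.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame of `nsim` simulated shielding columns.
#' @export
simulate.shift_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::fitted(object$lm)
  sd <- stats::sigma(object$lm)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), sd = sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Absolute referencing against a computed standard
#'
#' Shifts relative to a computed reference shielding (e.g. TMS):
#' `delta = sigma_ref - sigma`.
#'
#' @param sigma a [shielding_table()] or numeric shieldings.
#' @param sigma_ref reference shielding (ppm).
#' @return numeric shifts, or the table with a `delta_calc_ppm` column.
#' @export
reference_shifts <- function(sigma, sigma_ref) {
  if (!is.finite(sigma_ref)) stop("reference shielding must be finite")
  if (is.numeric(sigma)) return(sigma_ref - sigma)
  out <- as.data.frame(sigma)
  out$delta_calc_ppm <- sigma_ref - out$sigma_ppm
  out
}

#' Apply an additive shielding correction
#'
#' `sigma' = sigma + delta_sigma`, matched per nucleus.  Used identically
#' for molecular higher-level corrections, spin-orbit corrections, and the
#' MD DIFF correction; a missing entry is an error, never a silent zero.
#'
#' @param base a [shielding_table()].
#' @param delta correction data.frame with `system`, `nucleus`,
#'   `dsigma_ppm` (as produced by [diff_correction()]).
#' @return corrected [shielding_table()].
#' @export
apply_correction <- function(base, delta) {
  b <- as.data.frame(base)
  idx <- match(nucleus_key(b, delta), nucleus_key(delta, b))
  if (anyNA(idx)) {
    stop("no correction for: ",
         paste(paste0(b$nucleus[is.na(idx)], "(", b$system[is.na(idx)], ")"),
               collapse = ", "))
  }
  b$sigma_ppm <- b$sigma_ppm + delta$dsigma_ppm[idx]
  shielding_table(b)
}

#' Average two shielding tables
#'
#' Per-nucleus mean of two tables over the same nuclei (e.g. the two
#' crystallographic S-H orientations of l-cysteine, which are computed as
#' independent cluster builds and averaged).
#'
#' @param t1,t2 [shielding_table()]s with identical nucleus sets.
#' @return a [shielding_table()].
#' @export
average_tables <- function(t1, t2) {
  average_shieldings(list(t1, t2))
}

#' Reproduce the benchmark correlation tables
#'
#' One referencing fit per method (and element class): slope, intercept,
#' R^2, MAE, MaxAE with its nucleus, SDE, MSE, n.
#'
#' @param sigma a long [shielding_table()] spanning several methods.
#' @param exp an [experimental_shifts()] table.
#' @param methods methods to report (default: all present, input order).
#' @param element optional element filter.
#' @return data.frame of class `correlation_report`, one row per method.
#' @export
report_tables <- function(sigma, exp, methods = NULL, element = NULL) {
  s <- as.data.frame(sigma)
  if (!is.null(element)) s <- s[s$element == element, , drop = FALSE]
  if (is.null(methods)) methods <- unique(s$method)
  rows <- lapply(methods, function(m) {
    f <- fit_shieldings(shielding_table(s), exp, method = m)
    data.frame(method = m, slope = f$coefficients["slope"],
               intercept = f$coefficients["intercept"], r2 = f$r2,
               mae = f$mae, maxae = f$maxae, maxae_label = f$maxae_label,
               sde = f$sde, mse = f$mse, n = f$n)
  })
  if (!length(rows)) {
    out <- data.frame(method = character(), slope = numeric(),
                      intercept = numeric(), r2 = numeric(), mae = numeric(),
                      maxae = numeric(), maxae_label = character(),
                      sde = numeric(), mse = numeric(), n = integer())
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' Format a correlation report at display precision
#'
#' Rounds half-even at the conventional display precision (two decimals;
#' R^2 to four) and renders the display method names.
#'
#' @param report a `correlation_report`.
#' @return data.frame of formatted strings.
#' @export
format_report <- function(report) {
  disp <- c("DSD-PBEP86" = "DLPNO-DSD-PBEP86", "MP2" = "DLPNO-MP2")
  nm <- report$method
  nm[nm %in% names(disp)] <- disp[nm[nm %in% names(disp)]]
  data.frame(method = nm,
             slope = sprintf("%.2f", round(report$slope, 2)),
             intercept = sprintf("%.2f", round(report$intercept, 2)),
             r2 = sprintf("%.4f", round(report$r2, 4)),
             mae = sprintf("%.2f", round(report$mae, 2)),
             maxae = sprintf("%.2f %s", round(report$maxae, 2),
                             report$maxae_label),
             sde = sprintf("%.2f", round(report$sde, 2)))
}

#' @export
print.correlation_report <- function(x, ...) {
  print(format_report(x), row.names = FALSE)
  invisible(x)
}
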