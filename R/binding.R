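#' Quadratic tight-binding titration signal
#'
#' Fluorescence of a 1:1 complex titration where the titrant (p53 peptide)
#' and the fixed component (MDM2) are at comparable concentrations, so free
#' and total concentrations cannot be equated:
#' \deqn{F = F_0 + \frac{\Delta F_{max}}{2 [MDM2]_T}\left[
#'   (M_T + P_T + K_d) - \sqrt{(M_T + P_T + K_d)^2 - 4 M_T P_T}\right]}
#' The bracketed term is [complex]/known maximum; the discriminant is
#' clamped at zero before the square root to guard against floating-point
#' cancellation (algebraically it is non-negative).
#'
#' @param peptide_total_M Total titrant concentration(s) (M), >= 0.
#' @param mdm2_total_M Total fixed-component concentration (M), > 0.
#' @param Kd Dissociation constant (M), >= 0.
#' @param F0 Signal at zero titrant.
#' @param dFmax Maximal signal change at full saturation of MDM2.
#' @return Predicted signal at each titrant concentration.
#' @export
quadratic_binding_signal <- function(peptide_total_M, mdm2_total_M, Kd,
                                     F0, dFmax) {
  if (mdm2_total_M <= 0) stop("mdm2_total_M must be > 0")
  if (any(peptide_total_M < 0) || Kd < 0) {
    stop("concentrations and Kd must be >= 0")
  }
  s <- mdm2_total_M + peptide_total_M + Kd
  disc <- pmax(s^2 - 4 * mdm2_total_M * peptide_total_M, 0)
  F0 + dFmax / (2 * mdm2_total_M) * (s - sqrt(disc))
}

#' Subtract a peptide-only blank from a titration
#'
#' The intrinsic fluorescence of the titrated peptide is removed by
#' subtracting, point by point, the signal of a blank containing peptide
#' only. An inner-filter warning is raised when supplied absorbance
#' metadata exceeds 0.2.
#'
#' @param curve data.frame with \code{peptide_total_M}, \code{F}, and
#'   optionally \code{blank_F} and \code{absorbance}.
#' @return The curve with \code{F} blank-corrected.
#' @export
blank_subtract <- function(curve) {
  stopifnot(all(c("peptide_total_M", "F") %in% names(curve)))
  if (!is.null(curve$absorbance) && any(curve$absorbance > 0.2, na.rm = TRUE)) {
    warning("absorbance exceeds 0.2: inner-filter effects likely")
  }
  if (!is.null(curve$blank_F)) curve$F <- curve$F - curve$blank_F
  curve
}

#' Fit a fluorescence titration with the quadratic tight-binding model
#'
#' Least-squares estimation of (Kd, F0, dFmax) from one or more replicate
#' (titrant, signal) curves at a known fixed MDM2 concentration, using
#' [quadratic_binding_signal()]. Replicates are fitted jointly with shared
#' parameters. A fit whose Kd standard error exceeds Kd, or whose amplitude
#' is not significant at the 95\% level, is flagged poorly determined (the
#' regime of small fluorescence amplitudes).
#'
#' @param curve data.frame with \code{peptide_total_M} and \code{F}, or a
#'   list of such data.frames (replicates).
#' @param mdm2_total_M Fixed MDM2 concentration (M), > 0.
#' @return Object of class \code{"binding_fit"}: list with \code{Kd},
#'   \code{Kd_se}, \code{F0}, \code{dFmax}, their SEs, \code{mdm2_total_M},
#'   \code{poorly_determined}, \code{residuals}.
#' @export
fit_quadratic_binding <- function(curve, mdm2_total_M) {
  if (is.data.frame(curve)) curve <- list(curve)
  dat <- do.call(rbind, lapply(curve, function(d) {
    stopifnot(all(c("peptide_total_M", "F") %in% names(d)))
    d[, c("peptide_total_M", "F")]
  }))
  if (nrow(dat) < 6) stop("need at least 6 points")
  if (any(dat$peptide_total_M < 0)) stop("negative concentrations rejected")
  x <- dat$peptide_total_M
  y <- dat$F

  F0_0 <- mean(y[x == min(x)])
  dF0 <- mean(y[x == max(x)]) - F0_0
  if (abs(dF0) < .Machine$double.eps) dF0 <- stats::sd(y) + .Machine$double.eps
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ quadratic_binding_signal(x, mdm2_total_M, Kd, F0, dFmax),
      start = list(Kd = mdm2_total_M, F0 = F0_0, dFmax = dF0),
      lower = c(Kd = 0, F0 = -Inf, dFmax = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 1000)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop("binding fit did not converge: ", conditionMessage(fit),
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  poorly <- unname(se["Kd"]) > unname(cf["Kd"]) ||
    abs(cf["dFmax"]) <= 1.96 * se["dFmax"]
  out <- list(
    Kd = unname(cf["Kd"]), Kd_se = unname(se["Kd"]),
    F0 = unname(cf["F0"]), F0_se = unname(se["F0"]),
    dFmax = unname(cf["dFmax"]), dFmax_se = unname(se["dFmax"]),
    mdm2_total_M = mdm2_total_M,
    poorly_determined = poorly,
    residuals = as.numeric(stats::residuals(fit))
  )
  class(out) <- "binding_fit"
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Quadratic tight-binding fit ([MDM2]_T = %.3g M)\n",
              x$mdm2_total_M))
  cat(sprintf("  Kd = %.4g +/- %.2g M%s\n", x$Kd, x$Kd_se,
              if (x$poorly_determined) "  [poorly determined]" else ""))
  cat(sprintf("  F0 = %.4g  dFmax = %.4g\n", x$F0, x$dFmax))
  invisible(x)
}
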