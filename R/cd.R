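#' Mean residue ellipticity from raw CD signal
#'
#' Converts machine-units ellipticity (millidegrees) to mean residue
#' ellipticity, \eqn{[\Theta] = \theta / (10 \cdot c \cdot l \cdot N)}, in
#' deg cm^2 dmol^-1 residue^-1, with \eqn{c} the molar peptide
#' concentration, \eqn{l} the pathlength in cm and \eqn{N} the number of
#' residues (peptide bonds are approximated by residue count, the usual
#' short-peptide convention).
#'
#' @param theta_mdeg Ellipticity in millidegrees.
#' @param concentration_M Peptide concentration (M), > 0.
#' @param pathlength_cm Cuvette pathlength (cm), > 0.
#' @param n_residues Number of residues, > 0.
#' @return Mean residue ellipticity (deg cm^2 dmol^-1 residue^-1).
#' @examples
#' mean_residue_ellipticity(-10, 40e-6, 0.1, 13)
#' @export
mean_residue_ellipticity <- function(theta_mdeg, concentration_M,
                                     pathlength_cm, n_residues) {
  if (any(concentration_M <= 0)) stop("concentration_M must be > 0")
  if (any(pathlength_cm <= 0)) stop("pathlength_cm must be > 0")
  if (any(n_residues <= 0)) stop("n_residues must be > 0")
  theta_mdeg / (10 * concentration_M * pathlength_cm * n_residues)
}

#' Helix percentage from mean residue ellipticity at 222 nm
#'
#' Linear estimate 100 * mre222 / reference, where the reference is the
#' mean residue ellipticity of a 100\% helical peptide
#' (-31500 deg cm^2 dmol^-1). Values are clamped to [0, 100]; positive
#' ellipticities (no helix signal at all) map to 0 with a warning, since
#' the linear estimate is only meaningful for negative 222 nm bands.
#'
#' @param mre222 Mean residue ellipticity at 222 nm.
#' @param reference Full-helix reference value (default -31500).
#' @return Helix percentage in [0, 100].
#' @examples
#' helix_percent_from_mre(-2741)  # 8.7
#' @export
helix_percent_from_mre <- function(mre222,
                                   reference = p53_constants()$mre_full_helix) {
  pct <- 100 * mre222 / reference
  if (any(mre222 > 0)) {
    warning("positive ellipticity at 222 nm: helix percentage clamped to 0")
  }
  pmin(pmax(pct, 0), 100)
}

#' Two-state helix-coil ellipticity model for a TFE titration
#'
#' Predicted mean residue ellipticity at 222 nm as a function of \% TFE for
#' a two-state helix <-> coil equilibrium with TFE-linear free energy:
#' \deqn{[\Theta](x) = (\theta_{coil} + \theta_{helix} K) / (1 + K),\quad
#'   K = \exp(-( \Delta G_{water} - m x )/(R T))}
#' with \eqn{\Delta G_{water}} the helix-coil free energy in water
#' (cal mol^-1, positive = helix unfavourable), \eqn{m} the TFE m-value
#' (cal mol^-1 \%^-1) and x the TFE percentage (v/v).
#'
#' @param tfe_percent TFE concentration(s), \% v/v.
#' @param dG_water Helix-coil free energy in water (cal mol^-1).
#' @param m_value m-value (cal mol^-1 \%^-1), > 0.
#' @param theta_coil,theta_helix Coil/helix baselines (deg cm^2 dmol^-1).
#' @param temperature_K Temperature (K).
#' @param R_cal Gas constant (cal mol^-1 K^-1).
#' @return Predicted mean residue ellipticity at each \code{tfe_percent}.
#' @export
tfe_two_state_signal <- function(tfe_percent, dG_water, m_value, theta_coil,
                                 theta_helix,
                                 temperature_K = p53_constants()$temp_cd_K,
                                 R_cal = p53_constants()$R_cal) {
  if (m_value <= 0) stop("m_value must be > 0")
  K <- exp(-(dG_water - m_value * tfe_percent) / (R_cal * temperature_K))
  (theta_coil + theta_helix * K) / (1 + K)
}

#' Helix fraction in water from the helix-coil free energy
#'
#' @param dG_water Helix-coil free energy in water (cal mol^-1).
#' @param temperature_K Temperature (K).
#' @param R_cal Gas constant (cal mol^-1 K^-1).
#' @return Equilibrium helix fraction K/(1+K) with K = exp(-dG/(RT)).
#' @export
helix_fraction_from_dG <- function(dG_water,
                                   temperature_K = p53_constants()$temp_cd_K,
                                   R_cal = p53_constants()$R_cal) {
  K <- exp(-dG_water / (R_cal * temperature_K))
  K / (1 + K)
}

#' Fit a two-state TFE titration
#'
#' Nonlinear least-squares fit of (\% TFE, mre222) data to the two-state
#' helix-coil model of [tfe_two_state_signal()], yielding the m-value, the
#' free energy in water, the titration midpoint
#' \eqn{[TFE]_{1/2} = \Delta G_{water} / m} and the helix fraction in water.
#' Baselines are fitted as constants by default; a curve is flagged
#' non-sigmoidal (\code{sigmoidal = FALSE}, no population estimates) when
#' the fitted midpoint is not bracketed by the data or the fitted amplitude
#' \eqn{|\theta_{helix} - \theta_{coil}|} is not resolved above noise at the
#' 95\% level.
#'
#' @param curve data.frame with columns \code{tfe_percent} (in [0, 100]) and
#'   \code{mre222}.
#' @param temperature_K Temperature (K), default 278.15 (5 degC).
#' @param R_cal Gas constant (cal mol^-1 K^-1).
#' @return Object of class \code{"tfe_fit"}: a list with
#'   \code{tfe_half_percent}, \code{m_value}, \code{dG_water} (satisfying
#'   dG_water = tfe_half * m exactly), \code{theta_coil}, \code{theta_helix},
#'   \code{helix_fraction_water}, \code{sigmoidal}, \code{fit_errors},
#'   \code{residuals}, \code{temperature_K}.
#' @export
fit_tfe_titration <- function(curve,
                              temperature_K = p53_constants()$temp_cd_K,
                              R_cal = p53_constants()$R_cal) {
  stopifnot(is.data.frame(curve),
            all(c("tfe_percent", "mre222") %in% names(curve)))
  x <- curve$tfe_percent
  y <- curve$mre222
  if (length(x) < 6) stop("need at least 6 titration points")
  if (any(x < 0 | x > 100)) stop("tfe_percent must lie in [0, 100]")
  if (temperature_K <= 0) stop("temperature_K must be > 0")

  RT <- R_cal * temperature_K
  # starts: baselines from the curve extremes, midpoint from the
  # half-signal crossing, m from a plausible transition width
  th_c0 <- mean(y[order(x)][1:2])
  th_h0 <- mean(y[order(x, decreasing = TRUE)][1:2])
  half_level <- (th_c0 + th_h0) / 2
  x_half0 <- stats::approx(y, x, xout = half_level, ties = mean)$y
  if (is.na(x_half0)) x_half0 <- stats::median(x)
  m0 <- 4 * RT / max(diff(range(x)), 1)
  start <- list(dG = m0 * x_half0, m = m0, th_c = th_c0, th_h = th_h0)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ tfe_two_state_signal(x, dG, m, th_c, th_h, temperature_K, R_cal),
      start = start,
      lower = c(dG = -Inf, m = 1e-6, th_c = -Inf, th_h = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop("TFE titration fit did not converge: ", conditionMessage(fit),
         call. = FALSE)
  }

  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  names(se) <- names(cf)
  tfe_half <- unname(cf["dG"] / cf["m"])
  amp <- unname(cf["th_h"] - cf["th_c"])
  amp_se <- sqrt(sum(se[c("th_h", "th_c")]^2, na.rm = TRUE))
  bracketed <- tfe_half >= min(x) && tfe_half <= max(x)
  resolved <- is.finite(amp_se) && amp_se > 0 && abs(amp) > 1.96 * amp_se
  sigmoidal <- bracketed && resolved

  out <- list(
    tfe_half_percent = tfe_half,
    m_value = unname(cf["m"]),
    dG_water = tfe_half * unname(cf["m"]),
    theta_coil = unname(cf["th_c"]),
    theta_helix = unname(cf["th_h"]),
    helix_fraction_water = if (sigmoidal) {
      helix_fraction_from_dG(unname(cf["dG"]), temperature_K, R_cal)
    } else NA_real_,
    sigmoidal = sigmoidal,
    temperature_K = temperature_K,
    fit_errors = c(dG_water = unname(se["dG"]), m_value = unname(se["m"]),
                   theta_coil = unname(se["th_c"]),
                   theta_helix = unname(se["th_h"])),
    residuals = as.numeric(stats::residuals(fit))
  )
  class(out) <- "tfe_fit"
  out
}

#' @export
print.tfe_fit <- function(x, ...) {
  cat("Two-state TFE titration fit (T =", x$temperature_K, "K)\n")
  if (!x$sigmoidal) cat("  [non-sigmoidal: populations not reported]\n")
  cat(sprintf("  [TFE]1/2 = %.3g %%  m = %.4g cal/mol/%%  dG(water) = %.4g cal/mol\n",
              x$tfe_half_percent, x$m_value, x$dG_water))
  if (x$sigmoidal) {
    cat(sprintf("  helix fraction in water = %.3f\n", x$helix_fraction_water))
  }
  invisible(x)
}
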