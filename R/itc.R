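#' Construct an ITC experiment
#'
#' An injection-mode calorimetry experiment: peptide (syringe) titrated
#' into MDM2 (cell). The first injection is conventionally smaller (e.g.
#' 0.5 ul followed by 19 x 2 ul) and is excluded from fitting downstream,
#' not here. \code{active_fraction} scales the nominal cell concentration
#' to the binding-competent fraction (MDM2 preparations partially aggregate,
#' giving apparent stoichiometries well below 1 at face-value
#' concentration).
#'
#' @param cell_volume_L Cell volume (L), > 0.
#' @param syringe_conc_M Syringe (peptide) concentration (M), > 0.
#' @param cell_conc_M Cell (MDM2) concentration (M), > 0.
#' @param injection_volumes_L Ordered injection volumes (L), all > 0.
#' @param heats_ucal Per-injection heats (ucal), same length (optional
#'   until integration).
#' @param temperature_K Temperature (K), default 288.15 (15 degC).
#' @param active_fraction Fraction of cell material binding-competent,
#'   in (0, 1].
#' @return Object of class \code{"itc_experiment"}.
#' @export
itc_experiment <- function(cell_volume_L, syringe_conc_M, cell_conc_M,
                           injection_volumes_L, heats_ucal = NULL,
                           temperature_K = p53_constants()$temp_binding_K,
                           active_fraction = 1) {
  if (cell_volume_L <= 0) stop("cell volume must be > 0")
  if (syringe_conc_M <= 0) stop("syringe concentration must be > 0")
  if (cell_conc_M <= 0) stop("cell concentration must be > 0")
  if (any(injection_volumes_L <= 0)) stop("injection volumes must be > 0")
  if (active_fraction <= 0 || active_fraction > 1) {
    stop("active_fraction must lie in (0, 1]")
  }
  if (!is.null(heats_ucal) &&
      length(heats_ucal) != length(injection_volumes_L)) {
    stop("heats and injection volumes differ in length")
  }
  structure(
    list(cell_volume_L = cell_volume_L, syringe_conc_M = syringe_conc_M,
         cell_conc_M = cell_conc_M,
         injection_volumes_L = as.numeric(injection_volumes_L),
         heats_ucal = heats_ucal, temperature_K = temperature_K,
         active_fraction = active_fraction),
    class = "itc_experiment"
  )
}

# Per-injection totals in the cell under the displacement-dilution model:
# each injection of volume v displaces cell content, multiplying existing
# concentrations by (1 - v/V0), and delivers v/V0 of syringe material.
itc_concentrations <- function(cell_conc_M, syringe_conc_M, volumes_L,
                               cell_volume_L) {
  n <- length(volumes_L)
  M <- X <- numeric(n)
  m <- cell_conc_M; x <- 0
  for (i in seq_len(n)) {
    f <- 1 - volumes_L[i] / cell_volume_L
    m <- m * f
    x <- x * f + (volumes_L[i] / cell_volume_L) * syringe_conc_M
    M[i] <- m; X[i] <- x
  }
  data.frame(mdm2_M = M, peptide_M = X)
}

# Equilibrium complex concentration for totals (sites S, titrant X) at Kd.
complex_conc <- function(S, X, Kd) {
  s <- S + X + Kd
  (s - sqrt(pmax(s^2 - 4 * S * X, 0))) / 2
}

#' Predicted differential injection heats for a 1:1 isotherm
#'
#' Heat released by injection i is the enthalpy times the change in moles
#' of complex in the cell, with exact displacement bookkeeping: the
#' pre-injection complex is first diluted by (1 - v/V0), then the cell
#' re-equilibrates at the new totals. Binding-competent cell sites are
#' \code{n * active_fraction * cell_conc}.
#'
#' @param exp An [itc_experiment()].
#' @param KA Association constant (M^-1), > 0.
#' @param dH_kcal Binding enthalpy (kcal mol^-1).
#' @param n Stoichiometry multiplying the cell concentration.
#' @param dilution_heat_ucal Constant per-injection dilution heat (ucal).
#' @return Numeric vector of per-injection heats (ucal).
#' @export
itc_predicted_heats <- function(exp, KA, dH_kcal, n = 1,
                                dilution_heat_ucal = 0) {
  if (KA <= 0) stop("KA must be > 0")
  v <- exp$injection_volumes_L
  V0 <- exp$cell_volume_L
  conc <- itc_concentrations(n * exp$active_fraction * exp$cell_conc_M,
                             exp$syringe_conc_M, v, V0)
  B <- complex_conc(conc$mdm2_M, conc$peptide_M, 1 / KA)
  Bprev <- c(0, B[-length(B)])
  dB <- B - Bprev * (1 - v / V0)
  dH_kcal * 1e9 * V0 * dB + dilution_heat_ucal  # 1 kcal = 1e9 ucal
}

#' Integrate injection peaks from a raw power trace
#'
#' Simplified thermogram integration: for each inter-injection interval the
#' baseline is linearly interpolated between quiet windows (the last
#' fraction of the interval preceding each injection, where the signal has
#' returned to baseline), and the heat is the trapezoidal integral of
#' (power - baseline) over the interval. Intervals whose end has not
#' returned to within 5 noise SD of the local baseline are flagged as
#' overlapping peaks.
#'
#' @details Overlap detection compares each quiet-window level against the
#' global baseline level measured before the first injection: a peak that
#' has not decayed by its interval's end leaves its quiet window displaced.
#' This assumes the instrument baseline itself drifts little over the run,
#' adequate for a simplified integrator.
#'
#' @param time_s Uniformly sampled times (s).
#' @param power_ucal_s Differential power (ucal s^-1).
#' @param injection_times_s Injection start times, all inside the trace.
#' @param quiet_fraction Fraction of each interval treated as the
#'   pre-injection quiet window (default 0.15).
#' @return data.frame with \code{heat_ucal} and \code{overlap} flag per
#'   injection.
#' @export
integrate_peaks <- function(time_s, power_ucal_s, injection_times_s,
                            quiet_fraction = 0.15) {
  stopifnot(length(time_s) == length(power_ucal_s))
  if (any(injection_times_s < min(time_s) | injection_times_s > max(time_s))) {
    stop("injection times must lie within the trace")
  }
  dt <- diff(time_s)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop("trace must be uniformly sampled")
  }
  inj <- sort(injection_times_s)
  bounds <- c(inj, max(time_s))
  # baseline anchor per injection: median power over the quiet window
  # just before each boundary
  anchor_t <- anchor_p <- numeric(length(bounds))
  for (i in seq_along(bounds)) {
    span <- if (i == 1) bounds[1] - min(time_s) else bounds[i] - bounds[i - 1]
    w0 <- bounds[i] - quiet_fraction * span
    sel <- time_s >= w0 & time_s <= bounds[i]
    anchor_t[i] <- mean(time_s[sel])
    anchor_p[i] <- stats::median(power_ucal_s[sel])
  }
  pre <- power_ucal_s[time_s < inj[1]]
  base_global <- stats::median(pre)
  noise_sd <- stats::sd(pre)
  if (!is.finite(noise_sd)) noise_sd <- 0
  heats <- overlap <- numeric(length(inj))
  for (i in seq_along(inj)) {
    lo <- inj[i]; hi <- bounds[i + 1]
    sel <- time_s >= lo & time_s <= hi
    base <- stats::approx(anchor_t, anchor_p, xout = time_s[sel],
                          rule = 2)$y
    heats[i] <- pracma::trapz(time_s[sel], power_ucal_s[sel] - base)
    peak <- max(abs(power_ucal_s[sel] - base_global))
    overlap[i] <- abs(anchor_p[i + 1] - base_global) >
      max(5 * noise_sd, 0.02 * peak, 1e-12)
  }
  data.frame(heat_ucal = heats, overlap = as.logical(overlap))
}

#' Correct injection heats for the heat of dilution
#'
#' Subtracts the mean heat of the post-saturation plateau (the average heat
#' of the injections after the binding equilibrium has reached saturation)
#' from every injection. The plateau is the last \code{n_plateau}
#' injections; it is accepted when their spread is below \code{tol}, or,
#' when \code{tol} is NULL, when a regression of heat on injection index
#' over those points shows no significant trend at the 95\% level. Explicit
#' \code{plateau_idx} overrides detection.
#'
#' @param heats_ucal Per-injection heats (ucal).
#' @param n_plateau Number of trailing injections forming the plateau
#'   (default 4).
#' @param tol Absolute spread tolerance (ucal) or NULL for the trend test.
#' @param plateau_idx Explicit plateau indices (optional).
#' @return List with \code{corrected} heats and \code{dilution_heat_ucal}.
#' @export
dilution_correct <- function(heats_ucal, n_plateau = 4, tol = NULL,
                             plateau_idx = NULL) {
  n <- length(heats_ucal)
  if (is.null(plateau_idx)) {
    if (n < n_plateau + 1) stop("too few injections to detect a plateau")
    plateau_idx <- seq(n - n_plateau + 1, n)
    q <- heats_ucal[plateau_idx]
    ok <- if (!is.null(tol)) {
      diff(range(q)) <= tol
    } else {
      sl <- summary(stats::lm(q ~ seq_along(q)))$coefficients
      nrow(sl) < 2 || sl[2, "Pr(>|t|)"] > 0.05
    }
    if (!ok) {
      stop("no post-saturation plateau found; pass explicit plateau_idx",
           call. = FALSE)
    }
  }
  dil <- mean(heats_ucal[plateau_idx])
  list(corrected = heats_ucal - dil, dilution_heat_ucal = dil)
}

#' Fit the 1:1 ITC isotherm
#'
#' Least-squares fit of dilution-corrected per-injection heats to the
#' 1:1 isotherm of [itc_predicted_heats()]. Free parameters are
#' (n, log10 KA, dH); with \code{float_active_fraction = TRUE} the
#' stoichiometry is fixed at 1 and the binding-competent fraction of the
#' nominal cell concentration is fitted instead (the two parameterisations
#' are equivalent up to the n <-> active_fraction product). The first
#' injection is excluded by default. A Wiseman c-value (KA x n x [cell])
#' outside ~1-1000 flags the isotherm as poorly determined.
#'
#' @details Plateau subtraction removes the true dilution heat only once
#' binding is saturated; for weak binders (low Wiseman c) the plateau still
#' contains binding heat and its subtraction biases KA upward. Setting
#' \code{float_offset = TRUE} adds a constant per-injection offset as a
#' nuisance parameter, absorbing any residual mis-subtraction.
#'
#' @param exp An [itc_experiment()] carrying \code{heats_ucal}.
#' @param float_active_fraction Fit the active fraction instead of n.
#' @param exclude_first Drop the first (small) injection (default TRUE).
#' @param float_offset Also fit a constant per-injection heat offset
#'   (default FALSE).
#' @return Object of class \code{"thermo_result"}; see
#'   [thermo_decompose()] for the derived fields.
#' @export
fit_isotherm <- function(exp, float_active_fraction = FALSE,
                         exclude_first = TRUE, float_offset = FALSE) {
  stopifnot(inherits(exp, "itc_experiment"), !is.null(exp$heats_ucal))
  idx <- seq_along(exp$heats_ucal)
  if (exclude_first) idx <- idx[-1]
  q <- exp$heats_ucal

  # starts: c ~ 30 for KA; dH from the first included injection
  KA0 <- 30 / exp$cell_conc_M
  mol1 <- exp$injection_volumes_L[idx[1]] * exp$syringe_conc_M
  dH0 <- q[idx[1]] * 1e-9 / mol1
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -1

  model <- function(p) {
    off <- if (float_offset) p[["q0"]] else 0
    if (float_active_fraction) {
      e2 <- exp; e2$active_fraction <- p[["nf"]]
      itc_predicted_heats(e2, 10^p[["logKA"]], p[["dH"]], n = 1)[idx] + off
    } else {
      itc_predicted_heats(exp, 10^p[["logKA"]], p[["dH"]],
                          n = p[["nf"]])[idx] + off
    }
  }
  res_fn <- function(p) q[idx] - model(p)
  par0 <- c(logKA = log10(KA0), dH = dH0, nf = 1)
  lower <- c(logKA = 0, dH = -Inf, nf = 1e-3)
  if (float_offset) {
    par0 <- c(par0, q0 = 0)
    lower <- c(lower, q0 = -Inf)
  }
  fit <- minpack.lm::nls.lm(
    par = par0, fn = res_fn, lower = lower,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (fit$info %in% c(0, 5)) {
    stop("isotherm fit did not converge: ", fit$message, call. = FALSE)
  }
  p <- fit$par
  covm <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- if (!is.null(covm)) sqrt(diag(covm)) else rep(NA_real_, 3)
  names(se) <- names(p)

  n_eff <- if (float_active_fraction) 1 else p[["nf"]]
  af <- if (float_active_fraction) p[["nf"]] else exp$active_fraction
  cval <- 10^p[["logKA"]] * n_eff * af * exp$cell_conc_M
  out <- thermo_decompose(p[["logKA"]], p[["dH"]], exp$temperature_K)
  out$n <- if (float_active_fraction) NA_real_ else p[["nf"]]
  out$offset_ucal <- if (float_offset) p[["q0"]] else NA_real_
  out$active_fraction <- af
  out$c_value <- cval
  out$c_value_ok <- cval >= 1 && cval <= 1000
  out$fit_errors <- c(log10_KA = unname(se["logKA"]),
                      dH = unname(se["dH"]), n = unname(se["nf"]))
  out$residuals <- as.numeric(fit$fvec)
  if (!out$c_value_ok) {
    warning(sprintf("Wiseman c = %.3g outside ~1-1000: isotherm poorly determined",
                    cval))
  }
  out
}

#' Thermodynamic decomposition of a binding constant
#'
#' From log10 KA and dH at temperature T:
#' Kd = 10^(-log10 KA), dG = -RT ln(10) log10 KA, TdS = dH - dG, with
#' R = 1.987e-3 kcal mol^-1 K^-1. The identities Kd*KA = 1,
#' dG = -RT ln KA and TdS = dH - dG hold to machine precision by
#' construction.
#'
#' @param log10_KA Base-10 log of the association constant (KA in M^-1).
#' @param dH_kcal Binding enthalpy (kcal mol^-1).
#' @param temperature_K Temperature (K), > 0.
#' @return Object of class \code{"thermo_result"}: list with \code{KA},
#'   \code{log10_KA}, \code{Kd_M}, \code{dH_kcal}, \code{dG_kcal},
#'   \code{TdS_kcal}, \code{temperature_K}.
#' @export
thermo_decompose <- function(log10_KA, dH_kcal = NA_real_,
                             temperature_K = p53_constants()$temp_binding_K) {
  if (temperature_K <= 0) stop("temperature_K must be > 0")
  R <- p53_constants()$R_kcal
  dG <- -R * temperature_K * log(10) * log10_KA
  out <- list(
    log10_KA = log10_KA, KA = 10^log10_KA, Kd_M = 10^(-log10_KA),
    dH_kcal = dH_kcal, dG_kcal = dG, TdS_kcal = dH_kcal - dG,
    temperature_K = temperature_K
  )
  class(out) <- "thermo_result"
  out
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("1:1 binding thermodynamics at %.2f K\n", x$temperature_K))
  cat(sprintf("  log KA = %.3f   Kd = %.3g M\n", x$log10_KA, x$Kd_M))
  cat(sprintf("  dH = %.3f  dG = %.3f  TdS = %.3f kcal/mol\n",
              x$dH_kcal, x$dG_kcal, x$TdS_kcal))
  if (!is.null(x$n) && !is.na(x$n)) cat(sprintf("  n = %.3f\n", x$n))
  invisible(x)
}
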