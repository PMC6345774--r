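#' Construct a stopped-flow kinetic trace
#'
#' A time-resolved fluorescence trace with the mixing-chamber
#' concentrations attached. The pseudo-first-order validity flag records
#' whether MDM2 is in at least 8-fold excess over the peptide, the
#' condition under which the relaxation is single-exponential with rate
#' kobs = kon[MDM2] + koff.
#'
#' @param time_s Strictly increasing, non-negative times (s).
#' @param signal Fluorescence signal at each time.
#' @param mdm2_conc_M MDM2 concentration (M), > 0.
#' @param peptide_conc_M Peptide concentration (M), > 0.
#' @param n_averaged Number of raw traces averaged into this one.
#' @return Object of class \code{"kinetic_trace"}.
#' @export
kinetic_trace <- function(time_s, signal, mdm2_conc_M, peptide_conc_M,
                          n_averaged = 1L) {
  if (length(time_s) != length(signal)) stop("time and signal lengths differ")
  if (any(time_s < 0)) stop("negative times rejected")
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  if (mdm2_conc_M <= 0 || peptide_conc_M <= 0) {
    stop("concentrations must be > 0")
  }
  structure(
    list(time_s = as.numeric(time_s), signal = as.numeric(signal),
         mdm2_conc_M = mdm2_conc_M, peptide_conc_M = peptide_conc_M,
         n_averaged = as.integer(n_averaged),
         pseudo_first_order = mdm2_conc_M >= 8 * peptide_conc_M),
    class = "kinetic_trace"
  )
}

#' Average replicate kinetic traces
#'
#' Pointwise mean of replicate traces acquired on a common time base at the
#' same concentrations. Routine practice is to average at least four traces
#' before fitting; fewer triggers a warning.
#'
#' @param traces List of [kinetic_trace()] objects with identical time grids
#'   and concentrations.
#' @return A [kinetic_trace()] with \code{n_averaged} set to the count.
#' @export
average_traces <- function(traces) {
  stopifnot(length(traces) >= 1)
  t0 <- traces[[1]]
  for (tr in traces[-1]) {
    if (!isTRUE(all.equal(tr$time_s, t0$time_s)) ||
        tr$mdm2_conc_M != t0$mdm2_conc_M ||
        tr$peptide_conc_M != t0$peptide_conc_M) {
      stop("traces must share time grid and concentrations")
    }
  }
  if (length(traces) < 4) {
    warning("averaging fewer than 4 traces (", length(traces), ")")
  }
  sig <- rowMeans(vapply(traces, `[[`, numeric(length(t0$signal)), "signal"))
  kinetic_trace(t0$time_s, sig, t0$mdm2_conc_M, t0$peptide_conc_M,
                n_averaged = length(traces))
}

#' Fit a single-exponential relaxation
#'
#' Least-squares fit of \code{offset + amplitude * exp(-kobs * t)} to a
#' kinetic trace. Starting values are deterministic: the offset from the
#' tail mean, the rate from a log-linear regression of the early decay.
#' If the fitted amplitude is indistinguishable from zero at the 95\% level
#' (or the signal carries no decay at all) the fit errors with
#' "no exponential behaviour", the situation seen for non-binding peptides.
#'
#' @param trace A [kinetic_trace()] (or list with \code{time_s},
#'   \code{signal}).
#' @return List with \code{kobs}, \code{amplitude}, \code{offset}, their
#'   standard errors (\code{se}), \code{residuals} and \code{sigma}
#'   (residual standard deviation).
#' @export
fit_single_exponential <- function(trace) {
  t <- trace$time_s
  y <- trace$signal
  if (length(t) < 10) stop("need at least 10 points")

  offset0 <- mean(y[t >= stats::quantile(t, 0.9)])
  amp0 <- y[1] - offset0
  if (abs(amp0) < 1e-12 * max(abs(y) + 1e-300) || stats::sd(y) == 0) {
    stop("no exponential behaviour: flat trace", call. = FALSE)
  }
  early <- which((y - offset0) / amp0 > 0.05)
  k0 <- if (length(early) >= 3) {
    z <- log((y[early] - offset0) / amp0)
    max(-stats::coef(stats::lm(z ~ t[early]))[2], 1 / max(t))
  } else 1 / stats::median(t)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ off + A * exp(-k * t),
      start = list(off = offset0, A = amp0, k = unname(k0)),
      lower = c(off = -Inf, A = -Inf, k = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop("no exponential behaviour: fit did not converge", call. = FALSE)
  }
  cf <- stats::coef(fit)
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  if (abs(cf["A"]) <= 1.96 * se["A"]) {
    stop("no exponential behaviour: amplitude not significant at 95%",
         call. = FALSE)
  }
  if (max(t) < 3 / cf["k"]) {
    warning("trace spans less than 3/kobs; rate poorly constrained")
  }
  list(
    kobs = unname(cf["k"]), amplitude = unname(cf["A"]),
    offset = unname(cf["off"]),
    se = c(kobs = unname(se["k"]), amplitude = unname(se["A"]),
           offset = unname(se["off"])),
    residuals = as.numeric(stats::residuals(fit)),
    sigma = sm$sigma
  )
}

#' Fit the pseudo-first-order rate line
#'
#' Linear regression of observed rates on MDM2 concentration,
#' kobs = kon[MDM2] + koff: the slope is the association rate constant,
#' the intercept the dissociation rate constant, with standard errors from
#' the regression. Because koff is an extrapolation to the y-axis its
#' relative error is typically much larger than that of kon. Weighted
#' regression (weights 1/kobs_err^2) is available; unweighted is the
#' default.
#'
#' @param series data.frame with columns \code{mdm2_conc_M},
#'   \code{kobs_s}, optionally \code{kobs_err}.
#' @param weighted Use 1/kobs_err^2 weights (default FALSE).
#' @return Object of class \code{"rate_fit"}: list with \code{kon},
#'   \code{koff}, \code{kon_se}, \code{koff_se}, \code{kd_kinetic_M},
#'   \code{kd_se}, \code{negative_koff} flag.
#' @export
fit_pseudo_first_order <- function(series, weighted = FALSE) {
  stopifnot(all(c("mdm2_conc_M", "kobs_s") %in% names(series)))
  x <- series$mdm2_conc_M
  y <- series$kobs_s
  if (length(unique(x)) < 2) stop("need at least 2 distinct concentrations")
  if (length(unique(x)) < 3 || max(x) / min(x) < 2) {
    warning("fewer than 3 concentrations or < 2-fold span; extrapolated ",
            "koff will be poorly determined")
  }
  w <- if (weighted && !is.null(series$kobs_err)) {
    1 / series$kobs_err^2
  } else NULL
  fit <- stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  kon <- unname(cf[2]); koff <- unname(cf[1])
  kd <- kd_from_rates(kon, koff, unname(se[2]), unname(se[1]))
  out <- list(
    kon = kon, koff = koff,
    kon_se = unname(se[2]), koff_se = unname(se[1]),
    kd_kinetic_M = kd$kd, kd_se = kd$kd_err,
    negative_koff = koff < 0
  )
  class(out) <- "rate_fit"
  out
}

#' Kinetic dissociation constant from rate constants
#'
#' Kd = koff/kon, assuming a two-state binding reaction. The error is
#' propagated in quadrature,
#' \eqn{\sigma_{Kd} = Kd \sqrt{(\sigma_{kon}/kon)^2 + (\sigma_{koff}/koff)^2}};
#' a Monte-Carlo propagation over Gaussian draws of (kon, koff) is available
#' as an alternative.
#'
#' @param kon Association rate constant (M^-1 s^-1), > 0.
#' @param koff Dissociation rate constant (s^-1).
#' @param kon_se,koff_se Standard errors (optional).
#' @param method "quadrature" (default) or "montecarlo".
#' @param n_draws Draws for the Monte-Carlo method.
#' @return List with \code{kd} (M) and \code{kd_err}.
#' @export
kd_from_rates <- function(kon, koff, kon_se = NA, koff_se = NA,
                          method = c("quadrature", "montecarlo"),
                          n_draws = 1e5) {
  method <- match.arg(method)
  if (kon <= 0) stop("kon must be > 0")
  kd <- koff / kon
  if (is.na(kon_se) || is.na(koff_se)) {
    return(list(kd = kd, kd_err = NA_real_))
  }
  err <- if (method == "quadrature") {
    if (koff == 0) kon_se / kon * abs(kd) else {
      abs(kd) * sqrt((kon_se / kon)^2 + (koff_se / koff)^2)
    }
  } else {
    draws <- stats::rnorm(n_draws, koff, koff_se) /
      stats::rnorm(n_draws, kon, kon_se)
    stats::sd(draws)
  }
  list(kd = kd, kd_err = err)
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("kon  = %.4g +/- %.2g M^-1 s^-1\n", x$kon, x$kon_se))
  cat(sprintf("koff = %.4g +/- %.2g s^-1%s\n", x$koff, x$koff_se,
              if (x$negative_koff) "  [negative intercept]" else ""))
  cat(sprintf("Kd (koff/kon) = %.4g +/- %.2g M\n", x$kd_kinetic_M, x$kd_se))
  invisible(x)
}
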