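#' Parameters of a binding mechanism
#'
#' Three mass-action schemes for peptide (P) binding to MDM2 (M):
#' \describe{
#'   \item{two_state}{P + M <-> C, rates kon/koff.}
#'   \item{conformational_selection}{Pu <-> Ph (rates kf/ku, folding of the
#'     free peptide), then Ph + M <-> C (kon/koff): only the pre-formed
#'     helical conformer binds.}
#'   \item{induced_fit}{P + M <-> C* (kon/koff), then C* <-> C (first-order
#'     rates kon_star/koff_star): folding happens on the protein, via an
#'     intermediate complex.}
#' }
#' Rates not belonging to the chosen scheme must be left NULL.
#'
#' @param scheme One of "two_state", "conformational_selection",
#'   "induced_fit".
#' @param kon Association rate constant (M^-1 s^-1).
#' @param koff Dissociation rate constant (s^-1).
#' @param kf,ku Folding/unfolding rates of the free peptide (s^-1),
#'   conformational selection only.
#' @param kon_star,koff_star Isomerisation rates of the bound intermediate
#'   (s^-1), induced fit only.
#' @param conc0 Named initial concentrations (M). Recognised names:
#'   two_state P, M, C; conformational_selection Pu, Ph, M, C; induced_fit
#'   P, M, Cstar, C. Missing species start at 0.
#' @return Object of class \code{"mechanism_params"}.
#' @export
mechanism_params <- function(scheme = c("two_state",
                                        "conformational_selection",
                                        "induced_fit"),
                             kon, koff, kf = NULL, ku = NULL,
                             kon_star = NULL, koff_star = NULL,
                             conc0 = c()) {
  scheme <- match.arg(scheme)
  rates <- list(kon = kon, koff = koff, kf = kf, ku = ku,
                kon_star = kon_star, koff_star = koff_star)
  needed <- switch(scheme,
    two_state = c("kon", "koff"),
    conformational_selection = c("kon", "koff", "kf", "ku"),
    induced_fit = c("kon", "koff", "kon_star", "koff_star"))
  extra <- setdiff(names(Filter(Negate(is.null), rates)), needed)
  if (length(extra)) {
    stop("rates not in scheme '", scheme, "': ",
         paste(extra, collapse = ", "))
  }
  miss <- needed[vapply(rates[needed], is.null, logical(1))]
  if (length(miss)) stop("missing rates: ", paste(miss, collapse = ", "))
  if (any(unlist(rates[needed]) < 0)) stop("rate constants must be >= 0")
  species <- switch(scheme,
    two_state = c("P", "M", "C"),
    conformational_selection = c("Pu", "Ph", "M", "C"),
    induced_fit = c("P", "M", "Cstar", "C"))
  bad <- setdiff(names(conc0), species)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  if (any(conc0 < 0)) stop("concentrations must be >= 0")
  y0 <- stats::setNames(numeric(length(species)), species)
  y0[names(conc0)] <- conc0
  structure(c(rates[needed], list(scheme = scheme, conc0 = y0)),
            class = "mechanism_params")
}

mechanism_derivs <- function(params) {
  switch(params$scheme,
    two_state = function(t, y, p) {
      v <- params$kon * y["P"] * y["M"] - params$koff * y["C"]
      list(c(P = -v, M = -v, C = v))
    },
    conformational_selection = function(t, y, p) {
      vf <- params$kf * y["Pu"] - params$ku * y["Ph"]
      vb <- params$kon * y["Ph"] * y["M"] - params$koff * y["C"]
      list(c(Pu = -vf, Ph = vf - vb, M = -vb, C = vb))
    },
    induced_fit = function(t, y, p) {
      vb <- params$kon * y["P"] * y["M"] - params$koff * y["Cstar"]
      vi <- params$kon_star * y["Cstar"] - params$koff_star * y["C"]
      list(c(P = -vb, M = -vb, Cstar = vb - vi, C = vi))
    })
}

mechanism_moieties <- function(params) {
  switch(params$scheme,
    two_state = list(peptide = c("P", "C"), mdm2 = c("M", "C")),
    conformational_selection = list(peptide = c("Pu", "Ph", "C"),
                                    mdm2 = c("M", "C")),
    induced_fit = list(peptide = c("P", "Cstar", "C"),
                       mdm2 = c("M", "Cstar", "C")))
}

bound_species <- function(params) {
  switch(params$scheme,
    two_state = "C",
    conformational_selection = "C",
    induced_fit = c("Cstar", "C"))
}

#' Simulate a binding mechanism
#'
#' Deterministic integration of the mass-action rate equations of the
#' chosen scheme (stiff-capable lsoda). The probe signal is the weighted
#' total of bound peptide; by default all complex forms contribute equally,
#' mimicking a fluorophore that cannot distinguish the induced-fit
#' intermediate from the final complex. Conservation of both the peptide
#' and the MDM2 moiety is verified at every time point (1e-9 relative) as a
#' postcondition.
#'
#' @param params A [mechanism_params()].
#' @param t_end End time (s), > 0.
#' @param n_points Number of output points (default 500).
#' @param signal_weights Optional named weights over bound species.
#' @return Object of class \code{"scheme_trajectory"}: list with
#'   \code{time_s}, \code{conc} (matrix, one column per species),
#'   \code{signal}, \code{params}.
#' @export
simulate_mechanism <- function(params, t_end, n_points = 500,
                               signal_weights = NULL) {
  stopifnot(inherits(params, "mechanism_params"))
  if (t_end <= 0) stop("t_end must be > 0")
  moi <- mechanism_moieties(params)
  for (m in moi) {
    if (sum(params$conc0[m]) <= 0) {
      stop("each conserved moiety needs a nonzero initial concentration")
    }
  }
  times <- seq(0, t_end, length.out = n_points)
  sol <- deSolve::ode(y = params$conc0, times = times,
                      func = mechanism_derivs(params), parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-14)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed: istate = ", attr(sol, "istate")[1])
  }
  conc <- sol[, -1, drop = FALSE]
  for (nm in names(moi)) {
    tot <- rowSums(conc[, moi[[nm]], drop = FALSE])
    if (max(abs(tot - tot[1])) > 1e-9 * max(tot[1], 1e-300)) {
      stop("mass conservation violated for ", nm)
    }
  }
  bs <- bound_species(params)
  w <- stats::setNames(rep(1, length(bs)), bs)
  if (!is.null(signal_weights)) w[names(signal_weights)] <- signal_weights
  signal <- as.numeric(conc[, bs, drop = FALSE] %*% w[bs])
  structure(list(time_s = times, conc = conc, signal = signal,
                 params = params),
            class = "scheme_trajectory")
}

#' Apparent equilibrium dissociation constant of a scheme
#'
#' The dissociation constant an equilibrium experiment reports, referred to
#' total free peptide and total complex:
#' two-state koff/kon; conformational selection
#' (koff/kon) (1 + ku/kf) (the free pool is diluted by the non-binding
#' coil); induced fit (koff/kon) / (1 + kon_star/koff_star) (the bound pool
#' is enriched by the isomerised complex). A divergence between this and
#' the bare kinetic ratio koff/kon is the signature of a mechanism with
#' more than one step.
#'
#' @param params A [mechanism_params()].
#' @return Apparent Kd (M).
#' @export
apparent_kd_equilibrium <- function(params) {
  stopifnot(inherits(params, "mechanism_params"))
  if (params$kon <= 0) stop("kon must be > 0")
  kd0 <- params$koff / params$kon
  switch(params$scheme,
    two_state = kd0,
    conformational_selection = {
      if (params$kf <= 0) stop("kf must be > 0 for the partition term")
      kd0 * (1 + params$ku / params$kf)
    },
    induced_fit = {
      if (params$koff_star <= 0) {
        stop("koff_star must be > 0 for the partition term")
      }
      kd0 / (1 + params$kon_star / params$koff_star)
    })
}

#' Observed relaxation rate of a simulated trajectory
#'
#' Fits the probe signal of a pseudo-first-order trajectory with the
#' single-exponential fitter of the kinetics module and classifies the
#' relaxation as single-exponential when the residual structure is small
#' (RMS residual below \code{tol} of the fitted amplitude). Multi-phasic
#' relaxations (e.g. conformational selection with slow folding) fail that
#' test.
#'
#' @details The rate is extracted in two passes: a fit over the whole
#' trajectory classifies the relaxation, and a refit restricted to
#' t >= 1/kobs reports the asymptotic rate. For a scheme that is not
#' exactly first order (the binding partner depletes slightly even in
#' excess) the early transient biases a whole-trace fit, while the tail is
#' governed by the slowest eigenmode of the linearised system — the
#' quantity [relaxation_rates()] predicts.
#'
#' @param traj A [simulate_mechanism()] trajectory whose MDM2 is in excess.
#' @param tol Relative RMS residual threshold (default 0.01).
#' @return List with \code{kobs}, \code{single_exponential}, and the
#'   whole-trace exponential \code{fit}.
#' @export
extract_kobs <- function(traj, tol = 0.01) {
  stopifnot(inherits(traj, "scheme_trajectory"))
  fit <- fit_single_exponential(list(time_s = traj$time_s,
                                     signal = traj$signal))
  rel <- sqrt(mean(fit$residuals^2)) / abs(fit$amplitude)
  kobs <- fit$kobs
  sel <- traj$time_s >= 1 / fit$kobs
  if (sum(sel) >= 20) {
    tail_fit <- tryCatch(
      fit_single_exponential(list(time_s = traj$time_s[sel],
                                  signal = traj$signal[sel])),
      error = function(e) NULL)
    if (!is.null(tail_fit)) kobs <- tail_fit$kobs
  }
  list(kobs = kobs, single_exponential = rel < tol, fit = fit)
}

#' Relaxation rates from the linearised rate matrix
#'
#' Eigen-decomposition oracle for pseudo-first-order conditions: with the
#' MDM2 concentration held constant the scheme is linear in the remaining
#' species, and the nonzero eigenvalues of the rate matrix are the
#' relaxation rates. Used to cross-check the exponential fitter and to
#' predict multi-phasic behaviour.
#'
#' @param params A [mechanism_params()].
#' @param mdm2_conc_M Fixed MDM2 concentration (M).
#' @return Sorted positive relaxation rates (s^-1), slowest first.
#' @export
relaxation_rates <- function(params, mdm2_conc_M) {
  A <- switch(params$scheme,
    two_state = matrix(c(-params$kon * mdm2_conc_M, params$koff,
                         params$kon * mdm2_conc_M, -params$koff),
                       2, 2, byrow = TRUE),
    conformational_selection = matrix(c(
      -params$kf, params$ku, 0,
      params$kf, -params$ku - params$kon * mdm2_conc_M, params$koff,
      0, params$kon * mdm2_conc_M, -params$koff), 3, 3, byrow = TRUE),
    induced_fit = matrix(c(
      -params$kon * mdm2_conc_M, params$koff, 0,
      params$kon * mdm2_conc_M, -params$koff - params$kon_star,
      params$koff_star,
      0, params$kon_star, -params$koff_star), 3, 3, byrow = TRUE))
  ev <- Re(eigen(A, only.values = TRUE)$values)
  rates <- sort(-ev[-ev > 1e-12 * max(abs(ev))])
  rates
}
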