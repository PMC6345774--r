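#' Ground truth for a synthetic data set
#'
#' Bundle of known parameters, noise level and seed from which every
#' synthetic input type is generated, so each analysis stage can be tested
#' by parameter recovery. Identical (params, seed) yield bit-identical
#' output. The noise model is i.i.d. Gaussian on the signal throughout, the
#' standard assumption for shot-noise-dominated photomultiplier/CD/ITC data
#' at these signal levels.
#'
#' @param kind One of "kinetic_trace", "pfo_series", "fluor_titration",
#'   "tfe_titration", "itc_heats", "shift_table", "ensemble".
#' @param params Named list of model parameters (units as in the consuming
#'   generator's documentation).
#' @param noise_sd Gaussian noise SD in signal units (>= 0).
#' @param seed Integer seed.
#' @return Object of class \code{"ground_truth"}.
#' @export
ground_truth <- function(kind, params, noise_sd = 0, seed = 1L) {
  kinds <- c("kinetic_trace", "pfo_series", "fluor_titration",
             "tfe_titration", "itc_heats", "shift_table", "ensemble")
  if (!kind %in% kinds) stop("unknown kind: ", kind)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  pos <- intersect(names(params),
                   c("kobs", "kon", "koff", "Kd", "KA", "MDM2_total",
                     "m_value"))
  for (nm in pos) {
    if (any(params[[nm]] <= 0)) stop(nm, " must be strictly positive")
  }
  if (!is.null(params$helix_prob) &&
      any(params$helix_prob < 0 | params$helix_prob > 1)) {
    stop("helix_prob must lie in [0, 1]")
  }
  if (!is.null(params$active_fraction) &&
      (params$active_fraction <= 0 || params$active_fraction > 1)) {
    stop("active_fraction must lie in (0, 1]")
  }
  structure(list(kind = kind, params = params, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

check_kind <- function(truth, kind) {
  stopifnot(inherits(truth, "ground_truth"))
  if (truth$kind != kind) {
    stop("ground truth kind is '", truth$kind, "', need '", kind, "'")
  }
}

#' Generate a single-exponential stopped-flow trace
#'
#' signal(t) = offset + amplitude * exp(-kobs t) + N(0, noise_sd). Params:
#' \code{kobs} (s^-1, > 0), \code{amplitude}, \code{offset}, and optionally
#' \code{mdm2_conc_M}, \code{peptide_conc_M} (defaults 2 uM and 0.125 uM,
#' the study's mixing-chamber conditions).
#'
#' @param truth [ground_truth()] of kind "kinetic_trace".
#' @param times Strictly increasing non-negative times (s).
#' @return A [kinetic_trace()] with the truth attached as attribute
#'   \code{"truth"}.
#' @export
generate_kinetic_trace <- function(truth, times) {
  check_kind(truth, "kinetic_trace")
  p <- truth$params
  if (any(times < 0)) stop("negative times rejected")
  if (any(diff(times) <= 0)) stop("non-monotone times rejected")
  sig <- withr::with_seed(truth$seed, {
    p$offset + p$amplitude * exp(-p$kobs * times) +
      stats::rnorm(length(times), 0, truth$noise_sd)
  })
  tr <- kinetic_trace(times, sig,
                      mdm2_conc_M = p$mdm2_conc_M %||% 2e-6,
                      peptide_conc_M = p$peptide_conc_M %||% 0.125e-6)
  attr(tr, "truth") <- truth
  tr
}

#' Generate a fluorescence titration obeying the quadratic isotherm
#'
#' Signal from [quadratic_binding_signal()] plus Gaussian noise. Params:
#' \code{Kd}, \code{F0}, \code{dFmax}, \code{MDM2_total}.
#'
#' @param truth [ground_truth()] of kind "fluor_titration".
#' @param peptide_concs Ordered titrant concentrations (M), >= 0.
#' @return data.frame with \code{peptide_total_M}, \code{F}; truth attached
#'   as attribute.
#' @export
generate_fluor_titration <- function(truth, peptide_concs) {
  check_kind(truth, "fluor_titration")
  p <- truth$params
  if (any(peptide_concs < 0)) stop("negative concentrations rejected")
  F <- withr::with_seed(truth$seed, {
    quadratic_binding_signal(peptide_concs, p$MDM2_total, p$Kd, p$F0,
                             p$dFmax) +
      stats::rnorm(length(peptide_concs), 0, truth$noise_sd)
  })
  out <- data.frame(peptide_total_M = peptide_concs, F = F)
  attr(out, "truth") <- truth
  out
}

#' Generate a two-state TFE titration
#'
#' Mean residue ellipticity at 222 nm per \% TFE from the two-state
#' helix-coil model of [tfe_two_state_signal()] plus Gaussian noise.
#' Params: \code{dG_water} (cal/mol), \code{m_value} (cal/mol/\%, > 0),
#' \code{theta_coil}, \code{theta_helix}, \code{temperature_K} (default
#' 278.15).
#'
#' @param truth [ground_truth()] of kind "tfe_titration".
#' @param tfe_percents Ordered TFE percentages in [0, 100].
#' @return data.frame with \code{tfe_percent}, \code{mre222}; truth
#'   attached as attribute.
#' @export
generate_tfe_titration <- function(truth, tfe_percents) {
  check_kind(truth, "tfe_titration")
  p <- truth$params
  if (is.null(p$m_value) || p$m_value <= 0) stop("m_value must be > 0")
  if (any(tfe_percents < 0 | tfe_percents > 100)) {
    stop("tfe_percents must lie in [0, 100]")
  }
  tK <- p$temperature_K %||% p53_constants()$temp_cd_K
  y <- withr::with_seed(truth$seed, {
    tfe_two_state_signal(tfe_percents, p$dG_water, p$m_value, p$theta_coil,
                         p$theta_helix, tK) +
      stats::rnorm(length(tfe_percents), 0, truth$noise_sd)
  })
  out <- data.frame(tfe_percent = tfe_percents, mre222 = y)
  attr(out, "truth") <- truth
  out
}

#' Generate an ITC differential-heat sequence
#'
#' Per-injection heats from the 1:1 isotherm with displacement-dilution
#' bookkeeping ([itc_predicted_heats()]), a constant dilution heat, an
#' optional binding-competent fraction of the nominal cell concentration,
#' and Gaussian noise. The first injection is generated like any other;
#' excluding it is the fitter's decision. Params: \code{KA} (M^-1),
#' \code{dH} (kcal/mol), \code{n}, \code{dilution_heat} (ucal),
#' \code{active_fraction} in (0, 1].
#'
#' @param truth [ground_truth()] of kind "itc_heats".
#' @param schedule List with \code{injection_volumes_L},
#'   \code{cell_volume_L}, \code{syringe_conc_M}, \code{cell_conc_M}, and
#'   optionally \code{temperature_K}.
#' @return An [itc_experiment()] carrying the noisy heats and nominal
#'   (face-value) cell concentration; truth attached as attribute.
#' @export
generate_itc_heats <- function(truth, schedule) {
  check_kind(truth, "itc_heats")
  p <- truth$params
  exp_true <- itc_experiment(
    cell_volume_L = schedule$cell_volume_L,
    syringe_conc_M = schedule$syringe_conc_M,
    cell_conc_M = schedule$cell_conc_M,
    injection_volumes_L = schedule$injection_volumes_L,
    temperature_K = schedule$temperature_K %||%
      p53_constants()$temp_binding_K,
    active_fraction = p$active_fraction %||% 1
  )
  q <- itc_predicted_heats(exp_true, p$KA, p$dH, n = p$n %||% 1,
                           dilution_heat_ucal = p$dilution_heat %||% 0)
  q <- withr::with_seed(truth$seed,
                        q + stats::rnorm(length(q), 0, truth$noise_sd))
  out <- exp_true
  out$active_fraction <- 1  # face value: the analyst does not know it
  out$heats_ucal <- q
  attr(out, "truth") <- truth
  out
}

#' Generate a chemical-shift table
#'
#' Observed H-alpha shifts per residue as
#' delta_RC + helix_prob * full_helix_offset + noise, against
#' caller-supplied random-coil references (named by one-letter residue
#' code). Phospho-marked residues additionally receive HN rows shifted
#' downfield by \code{nh_downfield_ppm}, carrying the phospho flag.
#' Params: \code{helix_prob} (per-residue, recycled if scalar),
#' \code{full_helix_ppm} (default -0.39), \code{nh_downfield_ppm}
#' (default 0.2).
#'
#' @param truth [ground_truth()] of kind "shift_table".
#' @param sequence data.frame from [parse_peptide_sequence()].
#' @param rc_ha Named vector of random-coil H-alpha shifts (ppm) by residue
#'   code; every residue in the sequence must be covered.
#' @param rc_hn Optional named vector of random-coil HN shifts for the
#'   phospho rows (default 8.2 ppm for all).
#' @return data.frame with the shift-table columns (\code{residue_index},
#'   \code{residue_code}, \code{phospho}, \code{atom},
#'   \code{delta_obs_ppm}, \code{delta_rc_ppm}); truth attached as
#'   attribute.
#' @export
generate_shift_table <- function(truth, sequence, rc_ha, rc_hn = NULL) {
  check_kind(truth, "shift_table")
  p <- truth$params
  n <- nrow(sequence)
  hp <- rep_len(p$helix_prob, n)
  off <- p$full_helix_ppm %||% p53_constants()$halpha_full_helix_ppm
  nh_off <- p$nh_downfield_ppm %||% 0.2
  missing_ref <- setdiff(sequence$residue_code, names(rc_ha))
  if (length(missing_ref)) {
    stop("no random-coil reference for residue(s): ",
         paste(missing_ref, collapse = ", "))
  }
  rc <- unname(rc_ha[sequence$residue_code])
  obs <- withr::with_seed(truth$seed,
                          rc + hp * off + stats::rnorm(n, 0, truth$noise_sd))
  out <- data.frame(
    residue_index = sequence$residue_index,
    residue_code = sequence$residue_code,
    phospho = sequence$phospho, atom = "HA",
    delta_obs_ppm = obs, delta_rc_ppm = rc,
    stringsAsFactors = FALSE
  )
  if (any(sequence$phospho)) {
    ph <- sequence[sequence$phospho, ]
    rc_n <- if (is.null(rc_hn)) rep(8.2, nrow(ph)) else {
      unname(rc_hn[ph$residue_code])
    }
    out <- rbind(out, data.frame(
      residue_index = ph$residue_index, residue_code = ph$residue_code,
      phospho = TRUE, atom = "HN",
      delta_obs_ppm = rc_n + nh_off, delta_rc_ppm = rc_n,
      stringsAsFactors = FALSE
    ))
  }
  attr(out, "truth") <- truth
  out
}

# psi drawn uniformly over the coil region (60, 180) U (-180, -150):
# 120 + 30 degrees of width, excluding the alpha basin.
sample_coil_psi <- function(n) {
  w <- stats::runif(n, 0, 150)
  ifelse(w < 120, 60 + w, -180 + (w - 120))
}

#' Generate a peptide backbone ensemble
#'
#' Frames are built residue by residue: with probability helix_prob(i)
#' residue i receives alpha-helical dihedrals (phi = -60, psi = -45),
#' otherwise dihedrals drawn uniformly from the coil region
#' (phi in (-180, -50), psi in (60, 180) U (-180, -150), covering the
#' beta/PPII basins while excluding alpha). Cartesian coordinates use ideal
#' backbone geometry ([build_backbone()]). Params: \code{helix_prob}
#' (scalar or per-residue).
#'
#' @param truth [ground_truth()] of kind "ensemble".
#' @param n_frames Number of frames, >= 1.
#' @param n_residues Number of residues, >= 3.
#' @return List of class \code{"peptide_ensemble"} with \code{frames}
#'   (coordinate matrices, nm), \code{helical} (n_residues x n_frames
#'   logical matrix of the drawn assignments), \code{reference} (ideal
#'   helix of the same length), \code{truth}.
#' @export
generate_ensemble <- function(truth, n_frames, n_residues) {
  check_kind(truth, "ensemble")
  if (n_residues < 3) stop("n_residues must be >= 3")
  if (n_frames < 1) stop("n_frames must be >= 1")
  hp <- rep_len(truth$params$helix_prob, n_residues)
  res <- withr::with_seed(truth$seed, {
    helical <- matrix(stats::runif(n_residues * n_frames) < hp,
                      n_residues, n_frames)
    frames <- vector("list", n_frames)
    for (j in seq_len(n_frames)) {
      phi <- ifelse(helical[, j], -60, stats::runif(n_residues, -180, -50))
      psi <- ifelse(helical[, j], -45, sample_coil_psi(n_residues))
      frames[[j]] <- build_backbone(phi, psi)
    }
    list(frames = frames, helical = helical)
  })
  structure(list(frames = res$frames, helical = res$helical,
                 helix_prob = hp, reference = ideal_helix(n_residues),
                 truth = truth),
            class = "peptide_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
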