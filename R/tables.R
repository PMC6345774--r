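#' Peptide registry for the p53/MDM2 study
#'
#' The thirteen acetylated/amidated p53 transactivation-domain peptides
#' (residues Glu17-Asn29 of full-length p53). Sequence strings follow the
#' study's notation: lower-case letters are substitutions, "pt"/"ps" are
#' phospho-Thr18/phospho-Ser20, and peptides carry N-terminal acetyl and
#' C-terminal amide caps. Residue numbering follows full-length p53 (17-29).
#'
#' @return A data.frame with columns \code{peptide}, \code{sequence}.
#' @seealso [parse_peptide_sequence()] to expand the notation into
#'   per-residue codes and phospho marks.
#' @export
p53_peptides <- function() {
  data.frame(
    peptide = c("P53-WT", "P53-pTpS", "P53-pT", "P53-pS", "P53-E18",
                "P53-D20", "P53-E18-D20", "P53-E18-D20-E24-E25",
                "P53-E18-E20", "P53-D18", "P53-E20", "P53-D18-E20",
                "P53-D18-D20"),
    sequence = c("Ac-ETFSDLWKLLPEN-NH2", "Ac-EptFpsDLWKLLPEN-NH2",
                 "Ac-EptFSDLWKLLPEN-NH2", "Ac-ETFpsDLWKLLPEN-NH2",
                 "Ac-EeFSDLWKLLPEN-NH2", "Ac-ETFdDLWKLLPEN-NH2",
                 "Ac-EeFdDLWKLLPEN-NH2", "Ac-EeFdDLWeeLPEN-NH2",
                 "Ac-EeFeDLWKLLPEN-NH2", "Ac-EdFSDLWKLLPEN-NH2",
                 "Ac-ETFeDLWKLLPEN-NH2", "Ac-EdFeDLWKLLPEN-NH2",
                 "Ac-EdFdDLWKLLPEN-NH2"),
    stringsAsFactors = FALSE
  )
}

#' Parse a capped p53-peptide sequence string
#'
#' Expands the registry notation ("Ac-EptFpsDLWKLLPEN-NH2") into one row per
#' residue with full-length-p53 numbering starting at \code{first_residue}.
#' Upper-case letters are wild-type residues, lower-case letters are
#' substitutions, and the digraphs "pt"/"ps" mark phosphorylated Thr/Ser.
#'
#' @param sequence Sequence string with optional "Ac-" / "-NH2" caps.
#' @param first_residue Number of the first residue (default 17, Glu17).
#' @return data.frame with columns \code{residue_index}, \code{residue_code}
#'   (upper-case one-letter code), \code{phospho} (logical),
#'   \code{substituted} (logical).
#' @export
parse_peptide_sequence <- function(sequence, first_residue = 17L) {
  body <- sub("^Ac-", "", sub("-NH2$", "", sequence))
  chars <- strsplit(body, "")[[1]]
  code <- character(0); phospho <- logical(0); subst <- logical(0)
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "p" && i < length(chars) && chars[i + 1] %in% c("t", "s")) {
      code <- c(code, toupper(chars[i + 1]))
      phospho <- c(phospho, TRUE)
      subst <- c(subst, FALSE)
      i <- i + 2L
    } else {
      code <- c(code, toupper(chars[i]))
      phospho <- c(phospho, FALSE)
      subst <- c(subst, chars[i] %in% letters)
      i <- i + 1L
    }
  }
  data.frame(
    residue_index = seq(first_residue, length.out = length(code)),
    residue_code = code, phospho = phospho, substituted = subst,
    stringsAsFactors = FALSE
  )
}

#' Published CD/TFE helicity table
#'
#' Per-peptide results of the CD analysis at 5 degC: the TFE-titration
#' midpoint \code{tfe_half} (\% v/v) and \code{m_value}
#' (cal mol^-1 \%^-1) with fitting errors, the helix percentage in water
#' derived from the titration free energy, the helix percentage derived from
#' the mean residue ellipticity at 222 nm (\code{mre222}, deg cm^2 dmol^-1),
#' and the helix percentage from replica-exchange simulations of the
#' isolated peptides. \code{sigmoidal} records whether the TFE curve showed
#' a two-state transition; for the phosphorylated peptides and the quadruple
#' mutant it did not, so no titration parameters exist for those rows.
#' Rows whose derived water helicity is 1\% carry a 10\% error by convention.
#'
#' @return data.frame, one row per peptide.
#' @export
table_cd_helicity <- function() {
  df <- data.frame(
    peptide = c("P53-WT", "P53-pTpS", "P53-pT", "P53-pS", "P53-E18",
                "P53-D20", "P53-E18-D20", "P53-E18-D20-E24-E25",
                "P53-E18-E20", "P53-D18", "P53-E20", "P53-D18-E20",
                "P53-D18-D20"),
    tfe_half = c(7, NA, NA, NA, 14, 25, 15, NA, 24.5, 12.0, 25, 33, 9.8),
    tfe_half_err = c(7, NA, NA, NA, 5, 3, 1, NA, 0.9, 0.7, 2, 5, 0.8),
    m_value = c(130, NA, NA, NA, 103, 74, 135, NA, 420, 383, 231, 112, 263),
    m_value_err = c(50, NA, NA, NA, 42, 32, 18, NA, 390, 142, 141, 70, 47),
    helix_pct_tfe = c(16, NA, NA, NA, 7, 4, 3, NA, 1, 1, 1, 1, 1),
    helix_pct_tfe_err = c(3, NA, NA, NA, 1, 2, 1, NA, 10, 10, 10, 10, 10),
    helix_pct_mre = c(8.7, 8.1, 10.2, 14.6, 7.5, 9, 6.6, 0, 8.7, 10.5,
                      9.2, 11.4, 9),
    mre222 = c(-2741, -2547, -3213, -4614, -2380, -2811, -2100, 142.7,
               -2757, -3313, -2911, -3597, -2811),
    helix_pct_remd = c(7, 2.1, 2, 15, 2.8, 7.6, 6.7, NA, 5, 2.5, 10, 6, 4.7),
    stringsAsFactors = FALSE
  )
  df$sigmoidal <- !is.na(df$tfe_half)
  df
}

#' Published stopped-flow and fluorescence-titration table
#'
#' Kinetic rate constants at 15 degC from pseudo-first-order analysis
#' (peptide held at 0.125 uM, MDM2 in at least 8-fold excess), the
#' dissociation constant computed as koff/kon assuming a two-state binding
#' reaction, and the dissociation constant from equilibrium fluorescence
#' titrations (Trp23 emission at 315 nm, MDM2 fixed at 4 uM). The quadruple
#' mutant showed no exponential behaviour at any MDM2 concentration (all-NA
#' row). Errors are fitting errors from the slope and intercept of the
#' pseudo-first-order line.
#'
#' @return data.frame, one row per peptide; \code{kon_M_s} in M^-1 s^-1,
#'   \code{koff_s} in s^-1, dissociation constants in uM.
#' @export
table_kinetics <- function() {
  data.frame(
    peptide = c("P53-WT", "P53-E18", "P53-D20", "P53-E18-D20",
                "P53-E18-D20-E24-E25", "P53-E18-E20", "P53-D18", "P53-E20",
                "P53-D18-E20", "P53-D18-D20", "P53-pS", "P53-pT",
                "P53-pTpS"),
    kon_M_s = 1e6 * c(1.6, 3.8, 9.5, 4, NA, 2.7, 5, 9, 8, 11, 3.3, 2.8, 1.9),
    kon_err = 1e6 * c(0.1, 0.7, 0.9, 2, NA, 0.9, 3, 2, 2, 4, 0.8, 1.6, 1.1),
    koff_s = c(9.0, 16, 7, 18, NA, 17, 23, 8, 13, 20, 5, 20, 11),
    koff_err = c(0.3, 2, 2, 6, NA, 2, 9, 5, 4, 11, 1, 3, 2),
    kd_kinetic_uM = c(5.5, 4.2, 0.7, 4.0, NA, 6, 5.0, 0.9, 1.6, 1.8, 1.6,
                      7.0, 5.7),
    kd_kinetic_err = c(0.5, 0.9, 0.2, 3.0, NA, 2, 3.0, 0.6, 0.6, 1.2, 0.6,
                       4.0, 3.5),
    kd_fluor_uM = c(3.0, 2.3, 1.5, 8.3, NA, NA, NA, 0.7, 3.2, NA, 0.3,
                    3.0, 2.5),
    kd_fluor_err = c(1.2, 0.6, 0.4, 4.9, NA, NA, NA, 0.1, 0.9, NA, 0.1,
                     1.6, 0.9),
    stringsAsFactors = FALSE
  )
}

#' Published calorimetric table
#'
#' ITC results at 15 degC: binding enthalpy \code{dH_kcal} (kcal mol^-1),
#' \code{log10_KA}, the dissociation constant printed alongside it
#' (\code{kd_uM} = 1/KA in uM) and the entropic term \code{TdS_kcal}
#' (kcal mol^-1). The quadruple mutant and P53-E20 were not determined.
#'
#' @return data.frame, one row per peptide.
#' @export
table_itc <- function() {
  data.frame(
    peptide = c("P53-WT", "P53-E18", "P53-D20", "P53-E18-D20",
                "P53-E18-D20-E24-E25", "P53-E18-E20", "P53-D18", "P53-E20",
                "P53-D18-E20", "P53-D18-D20", "P53-pS", "P53-pT",
                "P53-pTpS"),
    dH_kcal = c(-10.07, -7.02, -10.24, -8.80, NA, -9.12, -18.39, NA,
                -9.90, -9.95, -9.73, -6.83, -4.81),
    log10_KA = c(5.73, 5.15, 5.24, 4.69, NA, 5.30, 4.72, NA, 5.23, 4.56,
                 5.71, 4.60, 4.60),
    kd_uM = c(1.8, 7.1, 5.7, 20.4, NA, 5.0, 19.0, NA, 5.9, 27.5, 1.9,
              25.1, 25.1),
    TdS_kcal = c(-3.23, -0.26, -3.36, -2.64, NA, -2.16, -12.19, NA, -3.03,
                 -3.96, -2.26, -0.79, 1.23),
    stringsAsFactors = FALSE
  )
}
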