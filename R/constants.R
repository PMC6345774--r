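#' Physical constants and study reference values
#'
#' Constants used throughout the analysis, exposed so that every module
#' shares a single definition:
#' \describe{
#'   \item{R_cal}{Gas constant, 1.987 cal mol^-1 K^-1 (helix-coil fits).}
#'   \item{R_kcal}{Gas constant, 1.987e-3 kcal mol^-1 K^-1 (ITC).}
#'   \item{temp_cd_K}{CD/TFE experiments are run at 5 degC (278.15 K).}
#'   \item{temp_binding_K}{Binding experiments (fluorescence, stopped-flow,
#'     ITC) are run at 15 degC (288.15 K), below the aggregation temperature
#'     of the MDM2 construct.}
#'   \item{mre_full_helix}{Mean residue ellipticity at 222 nm of a fully
#'     helical peptide, -31500 deg cm^2 dmol^-1 residue^-1.}
#'   \item{halpha_full_helix_ppm}{Mean H-alpha conformational shift of a
#'     fully formed helix, -0.39 ppm.}
#'   \item{random_coil_band_ppm}{|conformational shift| below which a
#'     residue is classed as random coil, 0.1 ppm.}
#' }
#'
#' @return A named list of constants.
#' @export
p53_constants <- function() {
  list(
    R_cal = 1.987,
    R_kcal = 1.987e-3,
    temp_cd_K = 278.15,
    temp_binding_K = 288.15,
    mre_full_helix = -31500,
    halpha_full_helix_ppm = -0.39,
    random_coil_band_ppm = 0.1
  )
}
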