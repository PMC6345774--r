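# Shared fixtures, built in code at test time.

# Plausible random-coil H-alpha reference shifts (ppm) by residue code for
# the Glu17-Asn29 sequence; only differences delta_obs - delta_rc matter.
rc_ha_refs <- c(E = 4.29, T = 4.35, F = 4.66, S = 4.50, D = 4.76,
                L = 4.38, W = 4.70, K = 4.36, P = 4.44, N = 4.75)

wt_sequence <- function() parse_peptide_sequence("Ac-ETFSDLWKLLPEN-NH2")

default_itc_schedule <- function() {
  list(cell_volume_L = 200e-6, syringe_conc_M = 300e-6,
       cell_conc_M = 20e-6,
       injection_volumes_L = c(0.5e-6, rep(2e-6, 19)))
}

# Independent brute-force 1:1 equilibrium: solve for complex concentration
# numerically instead of via the closed-form quadratic root.
solve_complex_uniroot <- function(M_T, P_T, Kd) {
  if (M_T == 0 || P_T == 0) return(0)
  f <- function(B) B * Kd - (M_T - B) * (P_T - B)
  stats::uniroot(f, c(0, min(M_T, P_T)), tol = .Machine$double.eps)$root
}
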