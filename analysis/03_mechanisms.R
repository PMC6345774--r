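#!/usr/bin/env Rscript
# Mass-action analysis of the binding mechanism: simulate the two-state,
# conformational-selection and induced-fit schemes at the WT rate
# constants, extract observed relaxation rates, and scan the induced-fit
# isomerisation constant K* to find the value reconciling the kinetic
# ratio (5.6 uM) with the equilibrium Kd (1.8 uM).

library(p53mdm2)
dir.create("results/mechanisms", recursive = TRUE, showWarnings = FALSE)

kon <- 1.6e6; koff <- 9.0

# observed rate under the stopped-flow conditions, per scheme
rows <- list()
p_ts <- mechanism_params("two_state", kon = kon, koff = koff,
                         conc0 = c(P = 0.125e-6, M = 2e-6))
ek <- extract_kobs(simulate_mechanism(p_ts, 1.0, 800))
rows$two_state <- data.frame(scheme = "two_state", kobs = ek$kobs,
                             single_exp = ek$single_exponential,
                             kd_eq_uM = apparent_kd_equilibrium(p_ts) * 1e6)

p_cs <- mechanism_params("conformational_selection", kon = kon,
                         koff = koff, kf = 0.5, ku = 0.5,
                         conc0 = c(Pu = 0.0625e-6, Ph = 0.0625e-6,
                                   M = 2e-6))
ek <- extract_kobs(simulate_mechanism(p_cs, 8, 1000))
rows$cs <- data.frame(scheme = "conformational_selection (slow folding)",
                      kobs = ek$kobs, single_exp = ek$single_exponential,
                      kd_eq_uM = apparent_kd_equilibrium(p_cs) * 1e6)

p_if <- mechanism_params("induced_fit", kon = kon, koff = koff,
                         kon_star = 210, koff_star = 100,
                         conc0 = c(P = 0.125e-6, M = 2e-6))
ek <- extract_kobs(simulate_mechanism(p_if, 1.0, 800))
rows$if_ <- data.frame(scheme = "induced_fit (K* = 2.1)", kobs = ek$kobs,
                       single_exp = ek$single_exponential,
                       kd_eq_uM = apparent_kd_equilibrium(p_if) * 1e6)
schemes <- do.call(rbind, rows)
write.csv(schemes, "results/mechanisms/schemes.csv", row.names = FALSE)
print(schemes, digits = 4, row.names = FALSE)

# K* scan: which isomerisation equilibrium reconciles 5.6 with 1.8 uM?
kstar <- seq(0.5, 5, by = 0.05)
kd_app <- vapply(kstar, function(ks) {
  p <- mechanism_params("induced_fit", kon = kon, koff = koff,
                        kon_star = ks * 100, koff_star = 100,
                        conc0 = c(P = 1e-6, M = 1e-6))
  apparent_kd_equilibrium(p) * 1e6
}, numeric(1))
scan <- data.frame(kstar = kstar, kd_apparent_uM = kd_app)
write.csv(scan, "results/mechanisms/kstar_scan.csv", row.names = FALSE)
best <- scan$kstar[which.min(abs(scan$kd_apparent_uM - 1.8))]
cat(sprintf("\nK* bringing the apparent Kd to the ITC value of 1.8 uM: %.2f\n",
            best))
cat("A silent post-binding folding step with K* ~ 2.1 therefore explains\n",
    "the kinetic-ratio (5.6 uM) vs equilibrium (1.8 uM) discrepancy.\n")
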