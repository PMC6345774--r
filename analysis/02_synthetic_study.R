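#!/usr/bin/env Rscript
# Full synthetic re-enactment of the study: for every peptide, generate
# TFE titrations, stopped-flow traces, fluorescence titrations and ITC
# heats from the published parameters as ground truth, re-fit them with
# the package, and emit the three report tables plus the kinetic-vs-ITC
# cross-check.

library(p53mdm2)

cfg <- study_config(seed = 20260930)
report <- suppressWarnings(run_study(cfg))
write_study_report(report, "results/synthetic_study")

cat("Synthetic study written to results/synthetic_study\n\n")
cat("Kinetic vs equilibrium Kd cross-check (non-two-state flags):\n")
print(report$cross_check, digits = 3)
flagged <- report$cross_check$peptide[which(report$cross_check$non_two_state)]
cat("\nPeptides whose kinetic-ratio Kd is irreconcilable with the ITC Kd\n",
    "under a one-step mechanism:", paste(flagged, collapse = ", "), "\n")
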