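#!/usr/bin/env Rscript
# Step 1 — simulate a trial-like cohort.
#
# Generates a 100-participant synthetic cohort under the default
# configuration: metformin-dominated baseline regimens, stratified
# permuted-block allocation (blocks of 2 and 4, sex x 100-kg stratum),
# HbA1c/weight trajectories with the configured intervention effects,
# guideline-caricature prescribing at 6 and 12 months, OGTT curves, and
# missing-at-random dropout. Writes the canonical long-format CSV.

library(glycman)

seed <- 2026
cfg <- sim_config(n = 100, include_ogtt = TRUE)
coh <- simulate_cohort(cfg, seed = seed)

dir.create("results", showWarnings = FALSE)
write_cohort(coh, "results/cohort.csv")

v0 <- coh$visits[coh$visits$timepoint_months == 0, ]
cat("Simulated", nrow(v0), "participants (seed", seed, "):",
    sum(v0$arm == "FMD"), "FMD /", sum(v0$arm == "control"), "control\n")
cat("Baseline HbA1c mean (SD):", round(mean(v0$hba1c_mmol_mol), 1),
    paste0("(", round(sd(v0$hba1c_mmol_mol), 1), ")"), "mmol/mol\n")
cat("On metformin at baseline:",
    round(100 * mean(!is.na(v0$drug_1_name))), "%\n")
lost <- nrow(coh$dropout)
cat("Lost to follow-up:", lost, "participants\n")
cat("Wrote results/cohort.csv (", nrow(coh$visits), "visits )\n")
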