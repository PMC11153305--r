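# Joint (medication x HbA1c) category encodings consistent with the
# published 12-month marginal tables. Rows: medication decreased / stable /
# increased; columns: HbA1c improved / stable / deteriorated. The
# (decreased, deteriorated) cell is the documented 2-participant tie-break.
printed_joint_itt <- list(
  FMD     = rbind(c(10, 5, 2), c(8, 10, 4), c(0, 4, 0)),
  control = rbind(c(2, 0, 0), c(1, 13, 6), c(3, 9, 5))
)

# joints among protocol-compliant FMD completers (n = 30); control unchanged
printed_joint_pp_fmd <- rbind(c(8, 4, 2), c(7, 5, 2), c(0, 2, 0))

# full trial-like fixture: 43 + 39 classifiable, 6 + 4 lost to follow-up,
# 7/2 stopped medication entirely, 1/10 gained an additional drug
make_printed_cohort <- function() {
  cohort_from_categories(
    printed_joint_itt,
    n_stopped = c(FMD = 7, control = 2),
    n_added = c(FMD = 1, control = 10),
    n_lost = c(FMD = 6, control = 4),
    compliant_joint = list(FMD = printed_joint_pp_fmd,
                           control = printed_joint_itt$control)
  )
}

# long visit frame with injected continuous treatment effects, for
# parameter-recovery checks of the mixed-model layer
make_effect_frame <- function(n, seed, cfg = sim_config(n = n)) {
  set.seed(seed)
  part <- generate_baseline(cfg)
  plan <- randomize(part, seed = sample.int(2^31 - 1, 1))
  part$arm <- plan$assignments$arm
  part$weight_stratum <- weight_stratum(part$weight_kg)
  base_mes <- pmax(rnorm(n, 0.6, 0.4), 0)
  fup <- simulate_trajectories(part, cfg, baseline_mes = base_mes)
  base <- data.frame(participant_id = part$participant_id,
                     timepoint_months = 0,
                     hba1c_mmol_mol = part$hba1c_mmol_mol,
                     weight_kg = part$weight_kg, mes = base_mes,
                     stringsAsFactors = FALSE)
  visits <- rbind(base, fup)
  merge(visits,
        part[, c("participant_id", "arm", "sex", "weight_stratum")],
        by = "participant_id")
}
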