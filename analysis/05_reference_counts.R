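#!/usr/bin/env Rscript
# Step 5 — reproduce the reference trial's printed categorical results.
#
# The trial this pipeline emulates published, for its 12-month endpoints,
# arm-by-category counts (and per-protocol counts) but no participant-level
# data. Those printed counts are used here as inputs: participants are
# encoded to realise a joint (medication x HbA1c) distribution consistent
# with all three published marginal tables — including the two
# tie-break participants (medication decreased, HbA1c deteriorated) — and
# the pipeline is run on the encoded cohort. The resulting tables and
# p-values should match the published ones exactly.

library(glycman)

joint_itt <- list(
  FMD     = rbind(c(10, 5, 2), c(8, 10, 4), c(0, 4, 0)),
  control = rbind(c(2, 0, 0), c(1, 13, 6), c(3, 9, 5)))
joint_pp_fmd <- rbind(c(8, 4, 2), c(7, 5, 2), c(0, 2, 0))

coh <- cohort_from_categories(
  joint_itt,
  n_stopped = c(FMD = 7, control = 2),
  n_added = c(FMD = 1, control = 10),
  n_lost = c(FMD = 6, control = 4),
  compliant_joint = list(FMD = joint_pp_fmd, control = joint_itt$control))

out <- list()
for (set in c("ITT", "PP")) {
  rep <- run_pipeline(coh, analysis_set = set, timepoint = 12,
                      fit_effects = FALSE)
  cat("==", set, "analysis: FMD", rep$n_classified[["FMD"]], "/ control",
      rep$n_classified[["control"]], "classified ==\n")
  for (nm in names(rep$association_tests)) {
    at <- rep$association_tests[[nm]]
    cat(sprintf("  %-22s %-18s p = %.4g\n", nm, at$test_used, at$p_value))
  }
  out[[set]] <- list(
    tables = rep$category_tables,
    two_by_two = rep$two_by_two,
    p_values = lapply(rep$association_tests, function(a)
      list(test = a$test_used, p = a$p_value)))
  cat("\n")
}
dir.create("results", showWarnings = FALSE)
jsonlite::write_json(out, "results/reference_endpoints.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Wrote results/reference_endpoints.json\n")
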