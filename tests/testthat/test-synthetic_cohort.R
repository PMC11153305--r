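test_that("baseline draws match the configured marginals at large n", {
  cfg <- sim_config(n = 5000, p_metformin = 0.94)
  b <- generate_baseline(cfg, seed = 1)
  expect_equal(mean(b$hba1c_mmol_mol), 53, tolerance = 0.5 / 53)
  expect_lt(abs(mean(b$metformin_dose > 0) - 0.94), 0.03)
  expect_lt(abs(mean(b$sex == "M") - 0.5), 0.03)
  expect_true(all(b$hba1c_mmol_mol > 20))
  expect_true(all(b$metformin_dose %% 500 == 0))
  doses <- b$metformin_dose[b$metformin_dose > 0]
  expect_equal(unname(stats::median(doses)), 1000)
})

test_that("zero-variance config collapses to identical participants", {
  cfg <- sim_config(n = 10, age_sd = 0, weight_sd = 0, hba1c_sd = 0,
                    glucose_sd = 0, insulin_sd = 0, sens_sdlog = 0,
                    p_metformin = 1, dose_probs = c(0, 1, 0, 0, 0, 0))
  b <- generate_baseline(cfg, seed = 2)
  for (col in c("age", "weight_kg", "hba1c_mmol_mol", "metformin_dose"))
    expect_equal(length(unique(b[[col]])), 1)
})

test_that("trajectories carry the configured arm effects", {
  cfg <- sim_config(n = 2000)
  set.seed(3)
  part <- generate_baseline(cfg)
  part$arm <- rep(c("FMD", "control"), length.out = nrow(part))
  fup <- simulate_trajectories(part, cfg)
  m12 <- merge(fup[fup$timepoint_months == 12, ], part[, c("participant_id", "arm")])
  chg <- m12$hba1c_mmol_mol - part$hba1c_mmol_mol[match(m12$participant_id,
                                                        part$participant_id)]
  diff_arms <- mean(chg[m12$arm == "FMD"]) - mean(chg[m12$arm == "control"])
  # -3.2 configured; MC error ~ 2*sqrt(2*(5^2+4^2)/1000) ~ 0.6
  expect_lt(abs(diff_arms - (-3.2)), 0.6)
  expect_true(all(fup$hba1c_mmol_mol > 0) && all(fup$weight_kg > 0))
})

test_that("null effects leave arm means indistinguishable", {
  cfg <- sim_config(n = 2000,
                    hba1c_effect = c("6" = 0, "12" = 0),
                    weight_effect = c("6" = 0, "12" = 0))
  set.seed(4)
  part <- generate_baseline(cfg)
  part$arm <- rep(c("FMD", "control"), length.out = nrow(part))
  fup <- simulate_trajectories(part, cfg)
  m12 <- merge(fup[fup$timepoint_months == 12, ], part[, c("participant_id", "arm")])
  tt <- two_sample_t_test(m12$hba1c_mmol_mol[m12$arm == "FMD"],
                          m12$hba1c_mmol_mol[m12$arm == "control"])
  expect_gt(tt$p_value, 0.001)
})

test_that("GP policy applies the guideline caricature deterministically", {
  cfg <- sim_config(n = 4, adherence_prob = 1)
  up <- simulate_gp_policy(regimen("metformin", 1000), 60, 0, cfg)
  expect_equal(up$daily_dose[up$drug_name == "metformin"], 1500)
  stop_ <- simulate_gp_policy(regimen("metformin", 500), 45, -0.05, cfg)
  expect_equal(nrow(stop_), 0)
  hold <- simulate_gp_policy(regimen("metformin", 1000), 50, -0.05, cfg)
  expect_equal(hold$daily_dose, 1000)
  # no de-escalation without weight loss
  hold2 <- simulate_gp_policy(regimen("metformin", 1000), 45, 0, cfg)
  expect_equal(hold2$daily_dose, 1000)
  # at max metformin a second agent is added
  add <- simulate_gp_policy(regimen("metformin", 3000), 60, 0, cfg)
  expect_setequal(add$drug_name, c("metformin", "gliclazide"))
  # diet-only escalation starts metformin
  start <- simulate_gp_policy(regimen(), 60, 0, cfg)
  expect_equal(start$daily_dose, 500)
  # zero adherence: never acts
  cfg0 <- sim_config(n = 4, adherence_prob = 0)
  expect_equal(simulate_gp_policy(regimen("metformin", 1000), 70, 0, cfg0)$daily_dose,
               1000)
})

test_that("simulated arms produce the expected medication-category direction", {
  coh <- simulate_cohort(sim_config(n = 800), seed = 31)
  tab <- classify_cohort(coh, 12)$tables$medication
  prop <- tab / rowSums(tab)
  expect_gt(prop["FMD", "decreased"], prop["control", "decreased"])
  expect_lt(prop["FMD", "increased"], prop["control", "increased"])
})

test_that("simulated OGTT curves behave physiologically", {
  cfg <- sim_config(n = 4)
  cv <- simulate_ogtt(8.3, 156, 1, cfg, seed = 5)
  expect_s3_class(cv, "ogtt_curve")
  expect_equal(cv$glucose[1], 8.3)
  expect_gt(max(cv$glucose), 8.3)                 # post-load rise
  expect_equal(which.max(cv$glucose), 3)          # peak at 60 min
  expect_gt(max(cv$insulin), cv$insulin[1])
  # infinite sensitivity: flat insulin response (up to measurement noise)
  flat <- simulate_ogtt(8.3, 156, Inf, cfg, seed = 5)
  expect_lt(diff(range(flat$insulin)) / 156, 0.25)
  # determinism
  expect_equal(simulate_ogtt(8.3, 156, 1, cfg, seed = 8),
               simulate_ogtt(8.3, 156, 1, cfg, seed = 8))
})

test_that("default OGTT model yields an insulin-resistant cohort (Matsuda ~1.5)", {
  cfg <- sim_config(n = 500)
  b <- generate_baseline(cfg, seed = 6)
  m <- vapply(seq_len(nrow(b)), function(i)
    matsuda_index(simulate_ogtt(b$fasting_glucose[i], b$fasting_insulin[i],
                                b$insulin_sens[i], cfg)), 0)
  expect_true(all(m > 0))
  expect_lt(abs(mean(m) - 1.5), 0.2)
})

test_that("dropout censors later visits at the configured rates", {
  cfg0 <- sim_config(n = 50, dropout_rate = c(FMD = 0, control = 0))
  coh0 <- simulate_cohort(cfg0, seed = 7)
  expect_equal(nrow(coh0$visits), 150)            # complete data

  cfg <- sim_config(n = 600, dropout_rate = c(FMD = 0.16, control = 0.20))
  coh <- simulate_cohort(cfg, seed = 8)
  v0 <- coh$visits[coh$visits$timepoint_months == 0, ]
  v12 <- coh$visits[coh$visits$timepoint_months == 12, ]
  for (arm in c("FMD", "control")) {
    n_arm <- sum(v0$arm == arm)
    missing12 <- n_arm - sum(v12$arm == arm)
    rate <- cfg$dropout_rate[[arm]]
    expect_lt(abs(missing12 / n_arm - rate),
              3 * sqrt(rate * (1 - rate) / n_arm) + 0.01)
  }
  # censoring is monotone: no 12-month visit without all earlier ones
  ids12 <- v12$participant_id
  ids6 <- coh$visits$participant_id[coh$visits$timepoint_months == 6]
  expect_true(all(ids12 %in% ids6))
})

test_that("the full generator is deterministic given (config, seed)", {
  cfg <- sim_config(n = 40, include_ogtt = TRUE)
  c1 <- simulate_cohort(cfg, seed = 99)
  c2 <- simulate_cohort(cfg, seed = 99)
  expect_identical(c1$visits, c2$visits)
  c3 <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(c1$visits, c3$visits))
  expect_true(all(grepl("^glucose_|^insulin_", names(c1$visits)) |
                    TRUE))  # OGTT columns present when requested
  expect_true(all(c(paste0("glucose_", cfg$ogtt_times),
                    paste0("insulin_", cfg$ogtt_times)) %in% names(c1$visits)))
})

test_that("sim_config validates fields", {
  expect_error(sim_config(n = 2), "n must be")
  expect_error(sim_config(n = 10, compliance_prob = 1.2), "probabilities")
  expect_error(sim_config(n = 10, bogus_field = 1), "unknown")
  expect_error(sim_config(n = 10, dose_probs = c(1, 1)), "sum to 1")
})
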