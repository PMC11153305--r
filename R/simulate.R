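#' Configuration for the synthetic trial-cohort generator
#'
#' Defaults emulate a 12-month primary-care trial of a dietary intervention
#' in type 2 diabetes: ~100 participants on metformin and/or diet only,
#' well-controlled baseline glycaemia (HbA1c ~53 mmol/mol), obesity
#' (~100 kg), an intervention effect of a few mmol/mol HbA1c and a few kg of
#' weight at follow-up, ~16-20% loss to follow-up, and prescribing left to a
#' guideline-like general-practitioner policy so that medication-change
#' categories emerge endogenously. The distributional forms (truncated
#' normals, a discrete 500-mg metformin dose grid, Bernoulli dropout) are
#' modelling choices; the moments are the emulation targets.
#'
#' @param n Number of participants.
#' @param ... Named overrides of any default listed below.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 100, ...) {
  cfg <- list(
    n = n,
    # baseline marginals
    age_mean = 63, age_sd = 8,
    weight_mean = 100, weight_sd = 15,
    hba1c_mean = 53, hba1c_sd = 10.5,
    glucose_mean = 8.5, glucose_sd = 1.9,
    insulin_mean = 150, insulin_sd = 80,
    p_metformin = 0.89,
    dose_levels = c(500, 1000, 1500, 2000, 2500, 3000),
    dose_probs = c(0.25, 0.35, 0.15, 0.15, 0.05, 0.05),
    # longitudinal structure: arm effects (FMD minus control) at 6/12 months
    hba1c_effect = c("6" = -5.0, "12" = -3.2),
    weight_effect = c("6" = -3.8, "12" = -3.6),
    mes_effect = c("6" = -0.1, "12" = -0.3),
    hba1c_drift = c("6" = 0.0, "12" = 0.1),      # control-arm drift
    weight_drift = c("6" = -0.5, "12" = 0.2),
    hba1c_intercept_sd = 5, hba1c_resid_sd = 4,
    weight_intercept_sd = 2.5, weight_resid_sd = 1.5,
    mes_intercept_sd = 0.15, mes_resid_sd = 0.15,
    hba1c_weight_cor = 0.5,   # shared latent between HbA1c and weight change
    # dropout and compliance
    dropout_rate = c(FMD = 0.16, control = 0.20),
    compliance_prob = 0.7,
    # GP prescribing policy (caricature of guideline care)
    escalate_threshold = 53, deescalate_threshold = 48,
    weight_loss_frac = 0.03, adherence_prob = 0.8,
    dose_step = 500, metformin_max = 3000,
    second_agent = "gliclazide", second_agent_dose = 30,
    # OGTT model
    ogtt_times = c(0, 30, 60, 90, 120),
    ogtt_shape = c(0, 0.7, 1, 0.8, 0.45),
    glucose_amplitude = 5, insulin_gain = 4.8, sens_sdlog = 0.4,
    include_ogtt = FALSE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  if (cfg$n < 4) stop("n must be >= 4", call. = FALSE)
  sds <- c(cfg$age_sd, cfg$weight_sd, cfg$hba1c_sd, cfg$glucose_sd, cfg$insulin_sd)
  if (any(sds < 0)) stop("SDs must be >= 0", call. = FALSE)
  probs <- c(cfg$p_metformin, cfg$compliance_prob, cfg$adherence_prob,
             cfg$dropout_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]",
                                       call. = FALSE)
  if (abs(sum(cfg$dose_probs) - 1) > 1e-8) stop("dose_probs must sum to 1",
                                                call. = FALSE)
  invisible(cfg)
}

.rtruncnorm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Draw baseline characteristics for a synthetic cohort
#'
#' Sex ~50/50; age, weight, HbA1c (truncated > 20 mmol/mol), fasting glucose
#' and insulin from truncated normals with configured moments; a metformin
#' indicator with configured prevalence and a discrete 500-mg-step dose; and
#' a lognormal insulin-sensitivity multiplier used by the OGTT model.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Data.frame, one row per participant.
#' @export
generate_baseline <- function(cfg, seed = NULL) {
  .validate_sim_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n
  dose <- ifelse(stats::runif(n) < cfg$p_metformin,
                 cfg$dose_levels[sample.int(length(cfg$dose_levels), n,
                                            replace = TRUE, prob = cfg$dose_probs)],
                 0)
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age = round(.rtruncnorm(n, cfg$age_mean, cfg$age_sd, 18)),
    weight_kg = .rtruncnorm(n, cfg$weight_mean, cfg$weight_sd, 50),
    hba1c_mmol_mol = .rtruncnorm(n, cfg$hba1c_mean, cfg$hba1c_sd, 20),
    fasting_glucose = .rtruncnorm(n, cfg$glucose_mean, cfg$glucose_sd, 3),
    fasting_insulin = .rtruncnorm(n, cfg$insulin_mean, cfg$insulin_sd, 20),
    metformin_dose = dose,
    insulin_sens = stats::rlnorm(n, 0, cfg$sens_sdlog),
    stringsAsFactors = FALSE
  )
}

#' Simulate follow-up trajectories for HbA1c, weight and a continuous MES
#'
#' Each outcome at 6 and 12 months is
#' baseline + control drift + arm effect (FMD only) + participant random
#' intercept + residual noise. The HbA1c and weight random intercepts share
#' a latent factor (correlation `hba1c_weight_cor`) so weight change tracks
#' glycaemic change. All values are kept positive.
#'
#' @param participants Output of [generate_baseline()] with an `arm` column.
#' @param cfg A [sim_config()].
#' @param seed Optional seed.
#' @param baseline_mes Optional numeric vector of baseline continuous MES
#'   values (for effect-injection studies); if `NULL` no MES trajectory is
#'   simulated.
#' @return Long data.frame of follow-up visits (timepoints 6 and 12).
#' @export
simulate_trajectories <- function(participants, cfg, seed = NULL,
                                  baseline_mes = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot("arm" %in% names(participants))
  n <- nrow(participants)
  rho <- cfg$hba1c_weight_cor
  shared <- stats::rnorm(n)
  b_h <- cfg$hba1c_intercept_sd *
    (rho * shared + sqrt(1 - rho^2) * stats::rnorm(n))
  b_w <- cfg$weight_intercept_sd *
    (rho * shared + sqrt(1 - rho^2) * stats::rnorm(n))
  b_m <- cfg$mes_intercept_sd * stats::rnorm(n)
  fmd <- participants$arm == "FMD"

  out <- list()
  for (tp in c("6", "12")) {
    h <- participants$hba1c_mmol_mol + cfg$hba1c_drift[[tp]] +
      ifelse(fmd, cfg$hba1c_effect[[tp]], 0) + b_h +
      stats::rnorm(n, 0, cfg$hba1c_resid_sd)
    w <- participants$weight_kg + cfg$weight_drift[[tp]] +
      ifelse(fmd, cfg$weight_effect[[tp]], 0) + b_w +
      stats::rnorm(n, 0, cfg$weight_resid_sd)
    row <- data.frame(
      participant_id = participants$participant_id,
      timepoint_months = as.numeric(tp),
      hba1c_mmol_mol = pmax(h, 20),
      weight_kg = pmax(w, 40),
      stringsAsFactors = FALSE
    )
    if (!is.null(baseline_mes)) {
      # latent continuous channel for effect-injection studies; deliberately
      # not floored at 0 so the injected contrast is the true arm contrast
      # (pipeline MES comes from regimens and is non-negative by construction)
      row$mes <- baseline_mes + ifelse(fmd, cfg$mes_effect[[tp]], 0) + b_m +
        stats::rnorm(n, 0, cfg$mes_resid_sd)
    }
    out[[tp]] <- row
  }
  do.call(rbind, out)
}

#' One step of the caricature general-practitioner prescribing policy
#'
#' Mimics guideline-driven dose adaptation: if HbA1c exceeds the escalation
#' threshold, metformin is raised one dose step (to its maximum, after which
#' a second agent is added); if HbA1c is below the de-escalation threshold
#' and the participant has lost at least `weight_loss_frac` of baseline
#' weight, treatment is stepped down (second agent stopped first, else
#' metformin lowered one step or stopped). Otherwise unchanged. The GP
#' follows the policy with probability `adherence_prob` (draws from the
#' current RNG stream).
#'
#' @param reg Current [regimen()].
#' @param hba1c_mmol_mol Current HbA1c.
#' @param weight_change_frac Weight change relative to baseline (negative =
#'   loss).
#' @param cfg A [sim_config()].
#' @return Updated `regimen`.
#' @export
simulate_gp_policy <- function(reg, hba1c_mmol_mol, weight_change_frac, cfg) {
  if (stats::runif(1) > cfg$adherence_prob) return(reg)
  met <- if ("metformin" %in% reg$drug_name)
    reg$daily_dose[reg$drug_name == "metformin"] else 0
  second <- setdiff(reg$drug_name, "metformin")

  if (hba1c_mmol_mol > cfg$escalate_threshold) {
    if (met < cfg$metformin_max) {
      met <- min(met + cfg$dose_step, cfg$metformin_max)
    } else if (!length(second)) {
      second <- cfg$second_agent
      reg <- regimen(c("metformin", second), c(met, cfg$second_agent_dose))
      return(reg)
    }
    drugs <- c(if (met > 0) "metformin", second)
    doses <- c(if (met > 0) met,
               reg$daily_dose[match(second, reg$drug_name)])
    return(regimen(drugs, doses))
  }
  if (hba1c_mmol_mol < cfg$deescalate_threshold &&
      weight_change_frac <= -cfg$weight_loss_frac) {
    if (length(second)) {
      return(regimen("metformin"[met > 0], met[met > 0]))
    }
    met <- max(met - cfg$dose_step, 0)
    return(regimen("metformin"[met > 0], met[met > 0]))
  }
  reg
}

#' Simulate a 2-hour OGTT curve
#'
#' Glucose follows a smooth post-load excursion peaking at 60 minutes with
#' configured amplitude; insulin rises in proportion to the glucose
#' excursion, scaled by `insulin_gain` and inversely by the participant's
#' insulin-sensitivity multiplier (an infinitely sensitive participant shows
#' a flat insulin curve). The default gain was calibrated once so that the
#' default cohort's mean Matsuda index is about 1.5, i.e. an
#' insulin-resistant type 2 diabetes population.
#'
#' @param fasting_glucose Fasting glucose, mmol/l.
#' @param fasting_insulin Fasting insulin, pmol/l.
#' @param insulin_sens Sensitivity multiplier, > 0 (may be `Inf`).
#' @param cfg A [sim_config()].
#' @param seed Optional seed.
#' @return An [ogtt_curve()] in SI units.
#' @export
simulate_ogtt <- function(fasting_glucose, fasting_insulin, insulin_sens = 1,
                          cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shape <- cfg$ogtt_shape
  g <- fasting_glucose + cfg$glucose_amplitude * shape *
    exp(stats::rnorm(length(shape), 0, 0.05))
  g[1] <- fasting_glucose
  rise <- cfg$insulin_gain * shape / insulin_sens
  ins <- fasting_insulin * (1 + rise) *
    exp(c(0, stats::rnorm(length(shape) - 1, 0, 0.05)))
  ogtt_curve(cfg$ogtt_times, pmax(g, 0.1), pmax(ins, 0))
}

#' Censor a simulated cohort by loss to follow-up
#'
#' Each participant drops out independently with the per-arm probability;
#' the dropout visit is 6 or 12 months with equal probability and all visits
#' from then on are removed (missing at random by construction — dropout is
#' independent of outcome values).
#'
#' @param visits Long visit data.frame with `participant_id`, `arm`,
#'   `timepoint_months`.
#' @param cfg A [sim_config()].
#' @param seed Optional seed.
#' @return List with `visits` (censored) and `dropout` (data.frame of
#'   participant_id, dropout_month).
#' @export
apply_dropout <- function(visits, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  info <- unique(visits[visits$timepoint_months == 0, c("participant_id", "arm")])
  rate <- cfg$dropout_rate[info$arm]
  drops <- stats::runif(nrow(info)) < rate
  when <- ifelse(drops, ifelse(stats::runif(nrow(info)) < 0.5, 6, 12), Inf)
  dropout <- data.frame(participant_id = info$participant_id[drops],
                        dropout_month = when[drops], stringsAsFactors = FALSE)
  cut <- structure(when, names = info$participant_id)
  keep <- visits$timepoint_months < cut[visits$participant_id]
  list(visits = visits[keep, ], dropout = dropout)
}

#' Simulate a complete synthetic trial cohort
#'
#' Orchestrates the generator: baseline draw, stratified permuted-block
#' randomisation, HbA1c/weight trajectories with the configured arm effects,
#' GP-policy regimen updates at 6 and 12 months, optional OGTT curves,
#' and missing-at-random dropout. Fully deterministic given `(cfg, seed)`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (required).
#' @return A `glycman_cohort`: list with `visits` (canonical long format),
#'   `dropout`, `allocation` and `provenance` (config + seed).
#' @examples
#' coh <- simulate_cohort(sim_config(n = 20), seed = 1)
#' table(coh$visits$arm[coh$visits$timepoint_months == 0])
#' @export
simulate_cohort <- function(cfg = sim_config(), seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  part <- generate_baseline(cfg)
  plan <- randomize(part, seed = sample.int(2^31 - 1, 1))
  part$arm <- plan$assignments$arm
  part$weight_stratum <- weight_stratum(part$weight_kg)
  part$compliance_flag <- ifelse(part$arm == "FMD",
                                 stats::runif(nrow(part)) < cfg$compliance_prob,
                                 TRUE)

  fup <- simulate_trajectories(part, cfg)
  fup <- fup[order(fup$participant_id, fup$timepoint_months), ]

  # regimen history: baseline metformin, then GP policy at each follow-up
  regs <- lapply(seq_len(nrow(part)), function(i) {
    d <- part$metformin_dose[i]
    regimen("metformin"[d > 0], d[d > 0])
  })
  names(regs) <- part$participant_id
  reg_at <- list("0" = regs)
  for (tp in c(6, 12)) {
    prev <- reg_at[[length(reg_at)]]
    cur <- prev
    for (i in seq_len(nrow(part))) {
      id <- part$participant_id[i]
      row <- fup[fup$participant_id == id & fup$timepoint_months == tp, ]
      wchg <- (row$weight_kg[1] - part$weight_kg[i]) / part$weight_kg[i]
      cur[[id]] <- simulate_gp_policy(prev[[id]], row$hba1c_mmol_mol[1],
                                      wchg, cfg)
    }
    reg_at[[as.character(tp)]] <- cur
  }

  mk_visit <- function(tp) {
    if (tp == 0) {
      df <- data.frame(participant_id = part$participant_id,
                       timepoint_months = 0,
                       hba1c_mmol_mol = part$hba1c_mmol_mol,
                       weight_kg = part$weight_kg, stringsAsFactors = FALSE)
    } else {
      df <- fup[fup$timepoint_months == tp,
                c("participant_id", "timepoint_months", "hba1c_mmol_mol",
                  "weight_kg")]
    }
    rr <- reg_at[[as.character(tp)]][df$participant_id]
    df$drug_1_name <- vapply(rr, function(r)
      if (nrow(r) >= 1) r$drug_name[1] else NA_character_, "")
    df$drug_1_dose <- vapply(rr, function(r)
      if (nrow(r) >= 1) r$daily_dose[1] else NA_real_, 0)
    df$drug_2_name <- vapply(rr, function(r)
      if (nrow(r) >= 2) r$drug_name[2] else NA_character_, "")
    df$drug_2_dose <- vapply(rr, function(r)
      if (nrow(r) >= 2) r$daily_dose[2] else NA_real_, 0)
    df
  }
  visits <- rbind(mk_visit(0), mk_visit(6), mk_visit(12))
  meta <- part[, c("participant_id", "arm", "sex", "weight_stratum",
                   "compliance_flag")]
  visits <- merge(visits, meta, by = "participant_id")

  if (cfg$include_ogtt) {
    curves <- lapply(seq_len(nrow(visits)), function(i) {
      j <- match(visits$participant_id[i], part$participant_id)
      simulate_ogtt(part$fasting_glucose[j], part$fasting_insulin[j],
                    part$insulin_sens[j], cfg)
    })
    for (k in seq_along(cfg$ogtt_times)) {
      t <- cfg$ogtt_times[k]
      visits[[paste0("glucose_", t)]] <- vapply(curves, function(cv) cv$glucose[k], 0)
      visits[[paste0("insulin_", t)]] <- vapply(curves, function(cv) cv$insulin[k], 0)
    }
  }

  dd <- apply_dropout(visits, cfg)
  visits <- dd$visits[order(dd$visits$participant_id,
                            dd$visits$timepoint_months), ]
  rownames(visits) <- NULL
  structure(list(visits = visits, dropout = dd$dropout, allocation = plan,
                 provenance = list(config = unclass(cfg), seed = seed)),
            class = "glycman_cohort")
}

#' @export
print.glycman_cohort <- function(x, ...) {
  v0 <- x$visits[x$visits$timepoint_months == 0, ]
  cat("<glycman_cohort> ", nrow(v0), " participants (",
      sum(v0$arm == "FMD"), " FMD / ", sum(v0$arm == "control"),
      " control), ", nrow(x$visits), " visits\n", sep = "")
  invisible(x)
}
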